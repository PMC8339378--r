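test_that("cross-instrument trait conflicts are detected with adjacency tolerance", {
  s <- fix_schema()
  # two instruments map the same trait to opposite ends
  p <- make_profile(list(c("hasExtraversion", "High Extraversion"),
                         c("hasExtraversion", "Low Extraversion")))
  rep <- check_consistency(p, s)
  expect_length(rep, 1L)
  expect_equal(rep[[1]]$kind, "cross-instrument-conflict")
  expect_equal(nrow(rep[[1]]$assertions), 2L)
  # adjacent levels are tolerated by default, not with tolerance 0
  p2 <- make_profile(list(c("hasExtraversion", "High Extraversion"),
                          c("hasExtraversion", "Medium Extraversion")))
  expect_length(check_consistency(p2, s), 0L)
  expect_length(check_consistency(p2, s, tolerance = 0L), 1L)
  # a two-level vocabulary conflicts on any distinct pair
  p3 <- make_profile(list(c("hasSleep", "Poor Sleep"),
                          c("hasSleep", "Good Sleep")))
  expect_length(check_consistency(p3, s), 1L)
  # single-instrument profile is consistent; absence is never inconsistent
  p4 <- make_profile(list(c("hasExtraversion", "High Extraversion")))
  expect_length(check_consistency(p4, s), 0L)
})

test_that("functional clashes and declared disjointness are reported", {
  s <- fix_schema()
  p <- person_profile("p")
  p <- assert_fact(p, s, "hasGender", "female")
  p <- assert_fact(p, s, "hasGender", "male")
  rep <- check_consistency(p, s)
  expect_true(any(vapply(rep, function(r) r$kind == "functional-clash", NA)))
  # same values in different waves do not clash
  q <- person_profile("q")
  q <- assert_fact(q, s, "hasGender", "female", wave = "pre")
  q <- assert_fact(q, s, "hasGender", "female", wave = "during")
  expect_length(check_consistency(q, s), 0L)
  # declared disjoint pair
  d <- make_profile(list(c("hasFoodDiet", "Balanced Diet"),
                         c("hasFoodDiet", "Poor Diet")))
  expect_true(any(vapply(check_consistency(d, s), function(r)
    r$kind == "disjointness-violation", NA)))
})

test_that("detection is monotone: adding assertions never removes a violation", {
  s <- fix_schema()
  p <- make_profile(list(c("hasExtraversion", "High Extraversion"),
                         c("hasExtraversion", "Low Extraversion")))
  n0 <- length(check_consistency(p, s))
  p <- assert_fact(p, s, "hasCulture", "Religion")
  p <- assert_fact(p, s, "hasMoodProcess", "Anxious Mood")
  expect_gte(length(check_consistency(p, s)), n0)
})

test_that("hypothesis testing returns per-profile verdicts and recountable summary", {
  s <- fix_schema()
  hyp <- parse_rule(s,
    "Person(?p) ^ hasExtraversion(?p, HighExtraversion) -> hasBehavioralInhibition(?p, LowBehavioralInhibition)",
    id = "hyp-1", theory = "hypothesis")
  profiles <- list(
    # data contradicts the hypothesis
    make_profile(list(c("hasExtraversion", "High Extraversion"),
                      c("hasBehavioralInhibition", "High Behavioral Inhibition")),
                 id = "a"),
    # data consistent with it
    make_profile(list(c("hasExtraversion", "High Extraversion"),
                      c("hasBehavioralInhibition", "Low Behavioral Inhibition")),
                 id = "b"),
    # hypothesis does not apply
    make_profile(list(c("hasExtraversion", "Low Extraversion")), id = "c"))
  res <- test_hypothesis(hyp, profiles, s)
  expect_equal(res$verdicts$verdict, c("inconsistent", "consistent", "consistent"))
  expect_equal(res$summary$n_inconsistent, 1L)
  expect_equal(res$reports$a[[1]]$kind, "inference-vs-input-conflict")
  # recount oracle: summary equals the sum of per-profile verdicts
  expect_equal(res$summary$n_consistent + res$summary$n_inconsistent,
               res$summary$n_profiles)
  expect_equal(res$summary$n_consistent,
               sum(res$verdicts$verdict == "consistent"))
  # the empty hypothesis is consistent with everything
  res0 <- test_hypothesis(list(), profiles, s)
  expect_equal(res0$summary$n_inconsistent, 0L)
})

test_that("injected contradictions are recovered with no false positives", {
  s <- fix_schema(); lx <- fix_lexicon(); cb <- fix_codebooks()
  g <- generate_cohort(generator_params(n = 60, seed = 19,
                                        inconsistency_rate = 0.25,
                                        change_rate = 0),
                       s, lx, cb)
  profiles <- read_survey(g$survey, s, cb, lx)
  for (pid in names(g$truth)) {
    rep <- check_consistency(profiles[[pid]], s)
    has <- any(vapply(rep, function(r)
      r$kind == "cross-instrument-conflict", NA))
    expect_equal(has, g$truth[[pid]]$contradiction, info = pid)
  }
})
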