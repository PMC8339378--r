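test_that("the in-text rules parse, with whitespace tolerance", {
  s <- fix_schema()
  r1 <- parse_rule(s, "consume(?p,LightFood) ^ hasActivity(?p,ModerateActivity) -> hasSleepHygiene(?p,HighSleepHygiene)")
  expect_length(r1$antecedent, 2L)
  expect_length(r1$consequent, 1L)
  expect_equal(r1$consequent[[1]]$args[[2]]$name, "cco:high-sleep-hygiene")
  # the hand-written spaced variant parses to the same structure
  r1b <- parse_rule(s, "consume (?p, Light Food) ^ has Activity(?p, ModerateActivity) - > has Sleep Hygiene(?p, high Sleep Hygiene)")
  expect_equal(r1b$antecedent[[1]]$predicate, r1$antecedent[[1]]$predicate)
  expect_equal(r1b$consequent[[1]]$args[[2]]$name,
               r1$consequent[[1]]$args[[2]]$name)
  r2 <- parse_rule(s, "Person(?x) ^ hasSleep(?x,?y) ^ PoorSleep(?y) ^ hasConscientiousness(?x,?z) -> LowConscientiousness(?z)")
  expect_length(r2$antecedent, 4L)
  expect_setequal(unique(atom_vars <- unlist(lapply(r2$antecedent, function(a)
    vapply(Filter(function(x) x$type == "var", a$args), `[[`, "", "name")))),
    c("x", "y", "z"))
})

test_that("parser rejects unsafe, unknown-vocabulary and malformed rules", {
  s <- fix_schema()
  expect_error(parse_rule(s, "Person(?x) -> hasSleep(?x,?y)"),
               class = "psychonto_safety_error")
  expect_error(parse_rule(s, "hasNoSuchRel(?p,Pain) -> Person(?p)"),
               class = "psychonto_vocabulary_error")
  expect_error(parse_rule(s, "consume(?p,NoSuchFood) -> Person(?p)"),
               class = "psychonto_vocabulary_error")
  expect_error(parse_rule(s, "Person(?x) hasSleep(?x,?y)"),
               class = "psychonto_parse_error")
  expect_error(parse_rule(s, "Person(?x) -> Person(?x) -> Person(?x)"),
               class = "psychonto_parse_error")
})

test_that("forward chaining fires the sleep-hygiene rules on fixtures", {
  s <- fix_schema(); rs <- fix_rulesets()
  p <- make_profile(list(c("consume", "Light Food"),
                         c("hasActivity", "Moderate Activity")))
  res <- apply_rules(p, s, rs)
  expect_true("cco:high-sleep-hygiene" %in% res$inferred$object)
  expect_equal(res$inferred$provenance, "inferred")
  expect_match(res$inferred$rule_id, "sleep-hygiene")
  # daytime napping triggers low sleep hygiene
  p2 <- make_profile(list(c("hasSleepBeh", "Daytime Napping")))
  expect_true("cco:low-sleep-hygiene" %in% apply_rules(p2, s, rs)$inferred$object)
  # empty rule set infers nothing
  expect_equal(nrow(apply_rules(p2, s, list())$inferred), 0L)
})

test_that("every mapped practice row fires its rule", {
  s <- fix_schema(); rs <- fix_rulesets()
  expect_length(rs[["sleep-hygiene"]], 14L)
  mapping <- yaml::read_yaml(system.file("extdata", "table4_mapping.yaml",
                                         package = "psychonto"))
  expect_length(mapping$rows, 14L)
  for (row in mapping$rows) {
    p <- make_profile(lapply(row$atoms, function(a)
      c(a$relation, a$concept)))
    inf <- apply_rules(p, s, rs["sleep-hygiene"])$inferred
    expect_true(cco_id(row$consequent) %in% inf$object,
                label = sprintf("row %d fires", row$row))
  }
})

test_that("the poor-sleep personality associations re-type the trait objects", {
  s <- fix_schema(); rs <- fix_rulesets()
  p <- make_profile(list(c("hasSleep", "Poor Sleep"),
                         c("hasConscientiousness", "Conscientiousness"),
                         c("hasNeuroticism", "Neuroticism")))
  inf <- apply_rules(p, s, rs["personality-sleep"])$inferred
  expect_true("cco:low-conscientiousness" %in% inf$object)
  expect_true("cco:high-neuroticism" %in% inf$object)
})

test_that("behavioral-inhibition completion matches the exhaustive enumeration", {
  s <- fix_schema(); rs <- fix_rulesets()
  for (e in c("Low", "Medium", "High")) for (a in c("Low", "Medium", "High")) {
    p <- make_profile(list(
      c("hasExtraversion", paste(e, "Extraversion")),
      c("hasTraitAnxiety", paste(a, "Trait Anxiety"))))
    inf <- apply_rules(p, s, rs["bis-completion"])$inferred
    got <- inf$object[inf$relation == "hasBehavioralInhibition"]
    want <- bis_oracle(e, a)
    if (is.na(want)) {
      expect_true(length(got) == 0L, info = sprintf("E=%s A=%s", e, a))
    } else {
      expect_equal(got, cco_id(paste(want, "Behavioral Inhibition")),
                   label = sprintf("E=%s A=%s", e, a))
    }
  }
})

test_that("fixpoint equals the naive restart-scan oracle on random profiles", {
  s <- fix_schema(); rs <- fix_rulesets()
  set.seed(101)
  for (i in 1:25) {
    p <- random_profile(size = sample(2:5, 1))
    got <- fixpoint_keys(apply_rules(p, s, rs)$profile)
    want <- naive_fixpoint(s, profile_facts(p), rs)
    expect_identical(got, want, label = sprintf("random profile %d", i))
  }
})

test_that("chaining is monotone, idempotent and order independent", {
  s <- fix_schema(); rs <- fix_rulesets()
  set.seed(202)
  flat <- unlist(unname(rs), recursive = FALSE)
  for (i in 1:10) {
    pool <- fact_pool()
    sel <- sample(length(pool), 4)
    p <- make_profile(pool[sel])
    full <- apply_rules(p, s, rs)
    # idempotence: a second pass over the fixpoint adds nothing
    expect_equal(nrow(apply_rules(full$profile, s, rs)$inferred), 0L)
    # monotone in the profile: fewer inputs never infer more
    p_sub <- make_profile(pool[sel[-1]])
    sub <- apply_rules(p_sub, s, rs)
    expect_true(all(fixpoint_keys(sub$profile) %in%
                      fixpoint_keys(full$profile)))
    # monotone in the rule set
    half <- apply_rules(p, s, flat[1:8])
    expect_true(all(fixpoint_keys(half$profile) %in%
                      fixpoint_keys(full$profile)))
    # order independence: shuffled rules reach the same fixpoint
    expect_identical(fixpoint_keys(apply_rules(p, s,
                       flat[sample(length(flat))])$profile),
                     fixpoint_keys(full$profile))
    # shuffled assertion insertion order too
    p_shuf <- make_profile(pool[sample(sel)])
    expect_identical(fixpoint_keys(apply_rules(p_shuf, s, rs)$profile),
                     fixpoint_keys(full$profile))
  }
})

test_that("derivations are replayable down to input assertions", {
  s <- fix_schema(); rs <- fix_rulesets()
  p <- make_profile(list(c("consume", "Light Food"),
                         c("hasActivity", "Moderate Activity")))
  inf <- apply_rules(p, s, rs)$inferred
  expect_true(all(nzchar(inf$support)))
  expect_match(inf$support[inf$object == "cco:high-sleep-hygiene"],
               "consume=cco:light-food", fixed = TRUE)
})

test_that("dataset completion reports first values and respects toggles", {
  s <- fix_schema(); rs <- fix_rulesets()
  p <- make_profile(list(c("hasExtraversion", "High Extraversion")))
  res <- infer_missing(p, s, rs)
  expect_equal(res$completed$relation, "hasBehavioralInhibition")
  expect_equal(res$completed$object, "cco:low-behavioral-inhibition")
  expect_match(res$completed$rule_id, "bis-completion")
  # a fully specified profile completes nothing
  p2 <- make_profile(list(c("hasExtraversion", "High Extraversion"),
                          c("hasBehavioralInhibition",
                            "Low Behavioral Inhibition")))
  expect_equal(nrow(infer_missing(p2, s, rs)$completed), 0L)
  # an inferred value conflicting with input is reported, input retained
  p3 <- make_profile(list(c("hasExtraversion", "High Extraversion"),
                          c("hasBehavioralInhibition",
                            "High Behavioral Inhibition")))
  res3 <- infer_missing(p3, s, rs)
  expect_gt(length(res3$conflicts), 0L)
  expect_true("cco:high-behavioral-inhibition" %in%
                res3$profile$assertions$object[
                  res3$profile$assertions$provenance == "input"])
  # toggling the preset off removes exactly its inferences
  rs_off <- toggle_theory(rs, "bis-completion", FALSE)
  expect_equal(nrow(infer_missing(p, s, rs_off)$completed), 0L)
  expect_error(toggle_theory(rs, "no-such-theory", TRUE),
               class = "psychonto_lookup_error")
  # toggle off then on restores the inference set exactly (involution)
  rs_on <- toggle_theory(rs_off, "bis-completion", TRUE)
  expect_identical(fixpoint_keys(infer_missing(p, s, rs_on)$profile),
                   fixpoint_keys(res$profile))
})

test_that("completion output is invariant under rule list permutation", {
  s <- fix_schema(); rs <- fix_rulesets()
  flat <- unlist(unname(rs), recursive = FALSE)
  p <- make_profile(list(c("hasExtraversion", "High Extraversion"),
                         c("hasSleep", "Poor Sleep"),
                         c("hasConscientiousness", "Conscientiousness")))
  base <- infer_missing(p, s, flat)
  base_keys <- fixpoint_keys(base$profile)
  set.seed(303)
  for (i in 1:20) {
    perm <- infer_missing(p, s, flat[sample(length(flat))])
    expect_identical(fixpoint_keys(perm$profile), base_keys)
    expect_setequal(perm$completed$object, base$completed$object)
  }
})

test_that("a preset removal equals the set difference of full recomputations", {
  s <- fix_schema(); rs <- fix_rulesets()
  p <- make_profile(list(c("hasExtraversion", "High Extraversion"),
                         c("hasSleepBeh", "Daytime Napping")))
  all_keys <- fixpoint_keys(infer_missing(p, s, rs)$profile)
  off_keys <- fixpoint_keys(
    infer_missing(p, s, toggle_theory(rs, "bis-completion", FALSE))$profile)
  lost <- setdiff(all_keys, off_keys)
  expect_identical(lost,
                   "hasBehavioralInhibition cco:low-behavioral-inhibition")
})
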