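test_that("the free-text feeling report categorizes into five distinct categories", {
  s <- fix_schema(); lx <- fix_lexicon()
  res <- categorize_record(s, lx, "bad, introverted, anxious, pain, and fat",
                           frame = "feeling-report")
  expect_equal(sum(vapply(res$results, function(r)
    r$status == "mapped", NA)), 5L)
  expect_equal(res$n_categories, 5L)
  expect_setequal(unname(res$category_labels),
                  c("Subjective Emotional Feeling", "Personality",
                    "Mood Process", "Bodily Feeling", "Body Image"))
  expect_length(res$unmapped, 0L)
  # compositional oracle: record categories equal per-token recomputation
  single <- vapply(c("bad", "introverted", "anxious", "pain", "fat"),
                   function(tk) categorize_token(s, lx, tk,
                                                 "feeling-report")$category, "")
  expect_setequal(res$categories, unname(single))
})

test_that("tokens always yield exactly one of mapped/unmapped/ambiguous", {
  s <- fix_schema(); lx <- fix_lexicon()
  expect_equal(categorize_token(s, lx, "", "feeling-report")$status, "unmapped")
  expect_equal(categorize_token(s, lx, "zzz-unknown", "feeling-report")$status,
               "unmapped")
  r <- categorize_record(s, lx, c("bad", "zzz"), frame = "feeling-report")
  expect_equal(r$unmapped, "zzz")
  expect_equal(nrow(r$profile$assertions), 1L)
  # equal-priority double entry is an ambiguity error, not arbitrary choice
  lx2 <- lx
  lx2$entries <- c(lx2$entries, list(list(
    surface = "bad", target = "cco:gloomy-mood", relation = "hasMoodProcess",
    frame = "feeling-report", as_value = FALSE, priority = 0L)))
  amb <- categorize_token(s, lx2, "bad", "feeling-report")
  expect_equal(amb$status, "ambiguous")
  expect_length(amb$candidates, 2L)
  # a higher priority breaks the tie deterministically
  lx2$entries[[length(lx2$entries)]]$priority <- 5L
  expect_equal(categorize_token(s, lx2, "bad", "feeling-report")$object,
               "cco:gloomy-mood")
})

test_that("the reporting frame disambiguates state from trait readings", {
  s <- fix_schema(); lx <- fix_lexicon()
  feel <- categorize_token(s, lx, "anxious", "feeling-report")
  trait <- categorize_token(s, lx, "anxious", "trait-report")
  expect_equal(feel$object, "cco:anxious-mood")
  expect_equal(feel$category, "cco:mood-process")
  expect_equal(trait$object, "cco:trait-anxiety")
  expect_equal(trait$category, "cco:personality")
})

test_that("instrument discretization matches a brute-force binning oracle", {
  s <- fix_schema(); cb <- fix_codebooks()
  set.seed(11)
  for (spec in list(c("BigFive", "extraversion"),
                    c("STAI-trait", "trait_anxiety"),
                    c("behavior-items", "diet"))) {
    sc <- cb[[spec[1]]]$scales[[spec[2]]]
    vals <- stats::runif(350, sc$scale[1], sc$scale[2])
    for (v in vals) {
      got <- map_instrument_response(s, cb, spec[1], spec[2], v)
      expect_identical(got$object, sc$bins$objects[[bin_oracle(v, sc$bins$cuts)]])
    }
  }
  # boundary: the upper bound lands in the top bin
  expect_equal(map_instrument_response(s, cb, "BigFive", "extraversion", 5)$object,
               "cco:high-extraversion")
  expect_error(map_instrument_response(s, cb, "BigFive", "extraversion", 6),
               class = "psychonto_range_error")
  expect_error(map_instrument_response(s, cb, "NoSuchScale", "x", 1),
               class = "psychonto_codebook_error")
})

test_that("the manikin scale yields a coordinate under hasAffect", {
  s <- fix_schema(); cb <- fix_codebooks()
  resp <- map_instrument_response(s, cb, "SAM", "affect",
                                  c(valence = 2, arousal = 8))
  expect_s3_class(resp$object, "cco_coordinate")
  p <- assert_fact(person_profile("p"), s, resp$relation, resp$object)
  expect_equal(p$assertions$object_kind, "coordinate")
  expect_equal(p$assertions$valence, 2)
})

test_that("affect cross-validation agrees with the quadrant/midpoint oracle", {
  s <- fix_schema()
  qt <- default_quadrant_table()
  mk <- function(emotion, v, a) {
    p <- person_profile("p")
    p <- assert_fact(p, s, "hasAffect", emotion)
    assert_fact(p, s, "hasAffect", coordinate(v, a))
  }
  # independent oracle: quadrant table + midpoint split at 5
  oracle <- function(emotion, v, a) {
    row <- qt[qt$concept == emotion, ]
    vs <- if (v > 5) "pos" else if (v < 5) "neg" else row$valence
    as <- if (a > 5) "high" else if (a < 5) "low" else row$arousal
    vs == row$valence && as == row$arousal
  }
  set.seed(21)
  for (i in 1:40) {
    emo <- sample(qt$concept, 1)
    v <- sample(1:9, 1); a <- sample(1:9, 1)
    got <- cross_validate_affect(mk(emo, v, a), s)
    expect_equal(got$status, "ok")
    expect_equal(got$pairs$agree, oracle(emo, v, a),
                 label = sprintf("%s (%d,%d)", emo, v, a))
  }
  # single-modality profiles are not applicable, not errors
  p <- assert_fact(person_profile("p"), s, "hasAffect", "Anxiety")
  expect_equal(cross_validate_affect(p, s)$status, "not-applicable")
})
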