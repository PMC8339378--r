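mk_events <- function(days, pol = "performed", wave = "during",
                      beh = "cco:learning-task", value = NA_character_) {
  data.frame(behavior = beh, day = days, polarity = pol, value = value,
             wave = wave, stringsAsFactors = FALSE)
}

test_that("frequency classification separates singular from habitual", {
  # one skipped assignment is a stand-alone singular event
  one <- classify_frequency(mk_events(3, pol = "omitted"))
  expect_equal(one$label, "singular")
  expect_equal(one$support, 1L)
  # skipping repeating daily over a week is a habitual pattern
  daily <- classify_frequency(mk_events(0:6, pol = "omitted"))
  expect_equal(daily$label, "habitual")
  expect_equal(daily$periodicity, 1)
  # every-other-day is periodic too
  expect_equal(classify_frequency(mk_events(seq(0, 12, by = 2)))$label,
               "habitual")
  # three scattered events over the window miss the regularity threshold
  expect_equal(classify_frequency(mk_events(c(0, 1, 13)))$label, "singular")
  # degenerate thresholds make a single event habitual
  expect_equal(classify_frequency(mk_events(5), k = 1, r = 0)$label,
               "habitual")
  # empty stream yields the no-pattern result
  none <- classify_frequency(data.frame(
    behavior = character(0), day = numeric(0), polarity = character(0),
    value = character(0), wave = character(0)))
  expect_equal(none$label, "none")
})

test_that("the habitual label is monotone in added occurrences", {
  set.seed(77)
  for (i in 1:30) {
    days <- sort(sample(0:13, sample(3:8, 1)))
    base <- classify_frequency(mk_events(days))
    extra <- sample(setdiff(0:13, days), 1)
    more <- classify_frequency(mk_events(sort(c(days, extra))))
    if (base$label == "habitual") {
      expect_equal(more$label, "habitual",
                   info = paste("days:", paste(days, collapse = ","),
                                "extra:", extra))
    }
  }
})

test_that("change detection needs an established pre-wave pattern", {
  # pre: finishes assignments immediately (habitual); during: one
  # postponement -> a grave behavior change
  ev <- rbind(mk_events(0:9, wave = "pre"),
              mk_events(4, pol = "omitted", wave = "during"))
  r <- detect_change(ev)
  expect_true(r$change)
  expect_equal(r$type, "singular-opposition")
  # one bad night pre, one bad night during: singular evidence grounds
  # no change judgement
  ev2 <- rbind(mk_events(2, wave = "pre", beh = "cco:sleep"),
               mk_events(3, wave = "during", beh = "cco:sleep"))
  expect_false(detect_change(ev2)$change)
  # identical habitual patterns across waves: no change
  ev3 <- rbind(mk_events(0:9, wave = "pre"), mk_events(0:9, wave = "during"))
  expect_false(detect_change(ev3)$change)
  # missing pre-wave data: judged with only the available information
  ev4 <- mk_events(0:9, wave = "during")
  r4 <- detect_change(ev4)
  expect_false(r4$change)
  expect_match(r4$note, "available information")
  # a habitual value shift (e.g. diet value) is a change
  ev5 <- rbind(mk_events(0:9, wave = "pre", beh = "cco:food-diet",
                         value = "balanced"),
               mk_events(0:9, wave = "during", beh = "cco:food-diet",
                         value = "poor"))
  r5 <- detect_change(ev5)
  expect_true(r5$change)
  expect_equal(r5$type, "habitual-shift")
})

test_that("well-being roll-ups match an independent per-component recount", {
  s <- fix_schema(); lx <- fix_lexicon()
  p <- make_profile(list(
    c("hasSleepHygiene", "High Sleep Hygiene"),
    c("hasExercise", "Regular Exercise"),
    c("hasFoodDiet", "Balanced Diet"),
    c("hasSubjEmotionalFeeling", "Feeling Bad"),
    c("hasEmotionProcess", "Compassion"),
    c("hasBodilyFeeling", "Pain")))
  wb <- evaluate_wellbeing(p, s, lx)
  expect_equal(wb$physical$verdict, "favorable on 3/3 components")
  expect_equal(wb$physical$sleep$status, "favorable")
  # independent recount of emotional contributions over the valence table
  signs <- lx$valence_signs
  objs <- p$assertions$object[p$assertions$object %in% names(signs)]
  expect_equal(wb$emotional$n_positive, sum(signs[objs] == "positive"))
  expect_equal(wb$emotional$n_negative, sum(signs[objs] == "negative"))
  expect_equal(wb$emotional$verdict, "mixed")
  # absent components are unknown, never defaulted
  empty <- evaluate_wellbeing(person_profile("e"), s, lx)
  expect_equal(empty$physical$verdict, "unknown")
  expect_equal(empty$emotional$verdict, "unknown")
  expect_equal(empty$physical$nutrition$status, "unknown")
  # rule-inferred sleep hygiene feeds the sleep component
  rs <- fix_rulesets()
  p2 <- make_profile(list(c("hasSleepBeh", "Daytime Napping")))
  p2 <- apply_rules(p2, s, rs)$profile
  expect_equal(evaluate_wellbeing(p2, s, lx)$physical$sleep$status,
               "unfavorable")
})
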