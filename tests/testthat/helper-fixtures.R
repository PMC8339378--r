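# Shared fixtures, built once per test run.

.fix <- new.env()

fix_schema <- function() {
  if (is.null(.fix$schema)) .fix$schema <- core_schema()
  .fix$schema
}

fix_lexicon <- function() {
  if (is.null(.fix$lexicon)) .fix$lexicon <- load_lexicon(schema = fix_schema())
  .fix$lexicon
}

fix_codebooks <- function() {
  if (is.null(.fix$codebooks)) {
    .fix$codebooks <- load_codebooks(schema = fix_schema())
  }
  .fix$codebooks
}

fix_rulesets <- function() {
  if (is.null(.fix$rulesets)) .fix$rulesets <- builtin_rulesets(fix_schema())
  .fix$rulesets
}

# profile with facts given as list of c(relation, object) pairs
make_profile <- function(facts, id = "t", wave = "during") {
  s <- fix_schema()
  p <- person_profile(id)
  for (f in facts) p <- assert_fact(p, s, f[[1]], f[[2]], wave = wave)
  p
}

# pool of assertable facts used by randomized rule-engine tests: mixes rule
# triggers, trait levels and inert facts
fact_pool <- function() {
  list(
    c("consume", "Light Food"),
    c("hasActivity", "Moderate Activity"),
    c("hasActivity", "Pre-Bedtime Mental Activity"),
    c("hasSleep", "Poor Sleep"),
    c("hasSleep", "Regular Wake Time"),
    c("hasSleep", "Irregular Sleep Schedule"),
    c("hasSleepBeh", "Daytime Napping"),
    c("hasConscientiousness", "Conscientiousness"),
    c("hasNeuroticism", "Neuroticism"),
    c("hasExtraversion", "Low Extraversion"),
    c("hasExtraversion", "Medium Extraversion"),
    c("hasExtraversion", "High Extraversion"),
    c("hasTraitAnxiety", "High Trait Anxiety"),
    c("hasTraitAnxiety", "Low Trait Anxiety"),
    c("hasExercise", "Regular Exercise"),
    c("hasCulture", "Religion"),
    c("hasMoodProcess", "Anxious Mood")
  )
}

random_profile <- function(size = 4, id = "r") {
  pool <- fact_pool()
  make_profile(pool[sample(length(pool), size)], id = id)
}
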