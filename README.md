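# psychonto

An executable ontology toolkit for psychological monitoring: it organizes
unstructured survey output — free-text feeling reports, psychometric
instrument scores, behavior diaries — into a formal Character–Behavior–
Situation (CBS) model, and reasons over it. The intended users are
researchers in psychology and mental-health informatics who want to
categorize heterogeneous person data against one concept hierarchy, test
hypotheses expressed as if–then rules against a dataset, complete missing
qualitative values by inference, and detect behavior change between two
observation waves (for example before and during a lockdown).

## What is inside

The package implements the three classical ontology components plus the
machinery around them:

* **T-Box** — `core_schema()` builds a rooted concept DAG (Person,
  Character, Behavior, Situation, Coordinate, Culture, Food, Well-Being,
  Disease) with a mental-emotional-functioning expansion (bodily
  feelings, emotion/mood processes, subjective feelings, appraisals,
  physiological responses), the personality cluster (five-factor traits
  plus trait anxiety and behavioral activation/inhibition), and a
  person-to-concept relation inventory including the deliberately dual
  `hasAffect` (discrete emotion *and* valence/arousal coordinate).
* **A-Box** — `person_profile()` / `assert_fact()` / `query_assertions()`:
  wave- and provenance-annotated assertion sets; conflicting inputs are
  stored and flagged, never overwritten.
* **Mapper** — `categorize_token()`, `categorize_record()`,
  `map_instrument_response()`, `cross_validate_affect()`: lexicon-driven
  categorization of free text under reporting frames, codebook-driven
  discretization of instrument scores into qualitative levels, and
  quadrant cross-validation of the two affect representations.
* **Rules** — `parse_rule()`, `apply_rules()`, `builtin_rulesets()`,
  `infer_missing()`, `toggle_theory()`: a positive-conjunctive `A -> C`
  rule language (`consume(?p,LightFood) ^ hasActivity(?p,ModerateActivity)
  -> hasSleepHygiene(?p,HighSleepHygiene)`) with forward chaining to
  fixpoint, subclass/sub-property closure, traceable derivations and
  toggleable theory presets (sleep hygiene, personality–sleep,
  behavioral-inhibition completion).
* **Behavior** — `classify_frequency()`, `detect_change()`,
  `evaluate_wellbeing()`: singular vs habitual classification of event
  streams, cross-wave change detection (a single event opposing an
  established habit is a change; a previous singular behavior is never
  evidence), and emotional/physical well-being roll-ups.
* **Consistency** — `check_consistency()`, `test_hypothesis()`:
  functional clashes, cross-instrument level conflicts,
  inference-vs-input conflicts; per-profile verdicts for a hypothesis
  rule set over a cohort.
* **I/O and simulation** — Turtle export/import with reified
  wave/provenance annotations, YAML lexicon/codebooks/config, CSV survey
  and event readers, a CLI (`inst/cli/psychonto.R`) with `schema`,
  `categorize`, `infer`, `check`, `change` and `simulate` subcommands,
  and a seeded synthetic cohort generator with ground-truth labels
  (`generate_cohort()`).

## A worked example

The categorization that motivates the design: a student answers the free
linguistic task "I feel..." with *bad, introverted, anxious, pain, and
fat*. Five tokens, five different kinds of psychological marker:

```r
library(psychonto)
s  <- core_schema()
lx <- load_lexicon(schema = s)
r  <- categorize_record(s, lx, "bad, introverted, anxious, pain, and fat",
                        frame = "feeling-report")
unname(r$category_labels)
#> [1] "Subjective Emotional Feeling" "Personality"
#> [3] "Mood Process"                 "Bodily Feeling"
#> [5] "Body Image"
r$n_categories
#> [1] 5
```

The ontology separates the report into a subjective emotional feeling
(*bad*), a perceived personality trait (*introverted*), a mood process
(*anxious*), a bodily feeling (*pain*) and a body-image characteristic
adaptation (*fat*) — no linguistic analysis, just lexicon lookup plus the
superclass chain.

Inference completes missing values and evaluates health behavior:

```r
rs <- builtin_rulesets(s)
p  <- person_profile("student-1")
p  <- assert_fact(p, s, "hasSleepBeh", "Daytime Napping")
p  <- assert_fact(p, s, "hasExtraversion", "High Extraversion")
infer_missing(p, s, rs)$completed[, c("relation", "object", "rule_id")]
#>                  relation                        object          rule_id
#> 1 hasBehavioralInhibition cco:low-behavioral-inhibition bis-completion-1
#> 2         hasSleepHygiene         cco:low-sleep-hygiene  sleep-hygiene-2
```

High extraversion forces low behavioral inhibition (regardless of
anxiety), and daytime napping triggers the low-sleep-hygiene rule; both
inferences carry the producing rule id and a replayable support trace.

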