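---
title: "An ontology toolkit for psychological state and trait markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ontology toolkit for psychological state and trait markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`psychonto` implements an executable Character–Behavior–Situation (CBS)
ontology: behavior is modelled as arising from the interaction of an
individual's character — trait markers such as personality, and state
markers such as affect and well-being — with the situation they are in.
The package separates the three classical ontology components:

* **T-Box** (`core_schema()`): a rooted DAG of concepts under the
  upper-level classes Person, Character, Behavior, Situation, Coordinate,
  Culture, Food, Well-Being and Disease, together with a relation
  inventory in which every relation runs from a person to a concept (or a
  literal). Character splits into exactly three clusters — characteristic
  adaptations, mental emotional functioning, and personality (the five
  FFM traits plus trait anxiety and the behavioral
  activation/inhibition pair). Affect is deliberately represented twice:
  `hasAffect` exists once with a discrete affective-process range and once
  with a valence/arousal coordinate range, so that list-choice emotions
  and pictorial manikin ratings can sit side by side and be
  cross-validated.
* **A-Box** (`person_profile()`, `assert_fact()`): per-person assertion
  sets tagged with a wave (`pre`/`during`, the two observation periods a
  disruption study compares) and a provenance (`input`, `inferred`,
  `preset`). Conflicting inputs are stored and flagged, never
  overwritten: the whole point of the consistency loop is to *inspect*
  contradictory evidence.
* **R-Box** (`check_consistency()`): functionality declarations,
  disjointness, and ordered qualitative level vocabularies
  (Low/Medium/High per trait and per sleep hygiene/quality concept;
  Poor/Good for sleep).

```{r}
library(psychonto)
s <- core_schema()
s
is_subclass_of(s, "Pain", "Bodily Feeling")
top_category(s, "Learning Task")
```

The learning concept is the one place the hierarchy is a DAG rather than a
tree: a learning task is represented both as a task (a situation) and as a
learning behavior, so `top_category()` reports all three factor groups.

## Categorization

The mapper turns unstructured survey output into assertions. A free-text
feeling report is tokenized on commas, each token is looked up in a
lexicon under a reporting *frame*, and the object's superclass chain
determines the reported category:

```{r}
lx <- load_lexicon(schema = s)
r <- categorize_record(s, lx, "bad, introverted, anxious, pain, and fat",
                       frame = "feeling-report")
unname(r$category_labels)
```

Two design choices matter here. First, frames disambiguate surface forms:
"anxious" in a feeling report is an anxious mood (a state), while in a
trait report it is trait anxiety. At equal lexicon priority an ambiguous
token is an explicit error, never an arbitrary pick, and unknown tokens
are returned as `unmapped` rather than silently dropped. Second, a token
may map either to a specific concept (then its direct superclass is the
category, e.g. *bad* → Feeling Bad → Subjective Emotional Feeling) or to a
class carrying the token as a literal value (then the class itself is the
category, e.g. *fat* → Body Image). This reproduces the intended reading
in which "fat" is a body-image value rather than a body-image subclass.

Instrument codebooks discretize numeric scores into qualitative levels —
the toolkit's contract is qualitative throughout. Cut-points default to
scale tertiles (a score equal to a cut falls into the upper bin); every
codebook can override them. Three screens have no natural concept with a
level vocabulary, and we map them to the nearest affect concepts:
depression (PHQ-2) to Gloomy Mood, state anxiety to Anxious Mood, and
alexithymia (TAS-20) to Appraisal Process, with the level carried as a
literal value. A "low" level on such a screen is treated as absence of
evidence in the well-being roll-up, not as negative affect.

Coordinate/discrete cross-validation splits the 1–9 manikin scale at its
midpoint (5): valence above the midpoint is positive, arousal above it is
high, and a component exactly on the midpoint is compatible with either
side. The expected quadrant per emotion ships as a configurable circumplex
table (`default_quadrant_table()`).

## Rules and inference

Rules are positive conjunctions of concept atoms `C(?x)` and property
atoms `R(?x, ?y)` joined by `^`, with an `->` arrow; the parser is
whitespace-tolerant because hand-written rules are (`has Sleep Hygiene`
and `- >` both parse). There is no negation and there are no built-ins:
"extraversion not high" is encoded through explicit level constants, which
keeps the fixpoint priority-free and order-independent. Concept-atom
matching respects subclass closure; property-atom matching additionally
respects sub-property closure (the per-trait relations such as
`hasConscientiousness` are sub-properties of `hasPersonality`, mirroring
the hierarchy-implied reading of trait relations).

A consequent concept atom over an object variable, as in
`... PoorSleep(?y) ^ hasConscientiousness(?x,?z) -> LowConscientiousness(?z)`,
re-types the bound trait object: the engine adds
`hasConscientiousness(person, LowConscientiousness)`. This realizes the
SWRL reading — the person's conscientiousness individual acquires the
level class — inside an assertion-set model without individuals.

Three presets ship (`builtin_rulesets()`):

* `sleep-hygiene`: all fourteen practice rows, normalized from prose to
  atoms by the versioned mapping table in
  `inst/extdata/table4_mapping.yaml` (prose rows name practices, not
  atoms, so the normalization is itself an artifact worth versioning).
* `personality-sleep`: poor sleep types conscientiousness low and
  neuroticism high — qualitative direction only, no magnitudes.
* `bis-completion`: high extraversion forces low behavioral inhibition
  *regardless of anxiety*; high trait anxiety forces high inhibition only
  at explicitly low or medium extraversion. Encoding the dominance as a
  guard rather than a rule priority keeps the semantics monotone. Over
  the nine extraversion × anxiety level combinations this yields Low
  inhibition in three cells, High in two, and no conclusion in four —
  open-world: nothing is concluded where the stated correlations say
  nothing.

`infer_missing()` recomputes inference from input-provenance assertions,
reports which relations gained their first value with the producing rule
chain (completion must be explainable), and reports — without resolving —
inferred values that contradict inputs. `toggle_theory()` switches whole
presets off, supporting theory-agnostic comparison.

The divergence guard caps iterations at `|rules| × (|concepts|+1)²`; for
positive conjunctive rules the fixpoint is reached far earlier and the
guard is unreachable.

## Behavior streams

Event streams are day-indexed occurrences with a polarity — an
omitted-but-scheduled act (a skipped assignment) is itself an event.
`classify_frequency()` labels a stream habitual when some contiguous
sub-span holds at least `k` occurrences (default 3) whose best-period
slot-fill fraction reaches `r` (default 0.6), with candidate periods
capped at span/`k`. The thresholds are configuration, not theory: the
underlying notion of "repeats over a specific time or periodically" is
deliberately open, so the defaults (3 occurrences, 60% regularity, 14-day
window) are surfaced in the config. Scoring the best sub-span rather than
the whole window makes the label provably monotone — an added occurrence
can never turn a habitual stream singular — which a whole-window fill
fraction does not guarantee (one late isolated event would dilute it).

`detect_change()` encodes the asymmetry of change evidence: a single
during-wave event opposing an established pre-wave habit (opposite
polarity, or a different qualitative value on the same behavior) is a
change; a pre-wave singular event grounds no change judgement whatsoever;
missing pre-wave data yields "no change, insufficient information" rather
than a guess. "Opposes" had to be operationalized — the source material
illustrates opposition but never defines it — and polarity/value
difference is the narrowest reading that covers the illustrations.
Downstream psychological interpretation (e.g. reading procrastination as
lack of motivation) is out of scope by design: the toolkit categorizes,
it does not diagnose.

Well-being summarization rolls up two of the six well-being dimensions —
emotional (affect-family assertions by valence sign, shipped with the
lexicon) and physical (nutrition, physical activity, sleep, including
rule-inferred sleep hygiene). Contributions are counted, not weighted,
and components without evidence are reported unknown, never defaulted.

## Consistency and hypothesis testing

`check_consistency()` reports functional clashes, disjoint qualitative
levels on one concept (cross-instrument conflicts when both values are
inputs, inference-vs-input conflicts otherwise) and declared disjoint
pairs. Level conflicts use an adjacency tolerance: by default High vs Low
conflicts while High vs Medium does not, because instruments discretized
onto a coarse scale legitimately disagree by one step; two-level
vocabularies (Poor/Good sleep) conflict on any distinct pair. The
tolerance is configurable down to 0 (any distinct pair conflicts).

`test_hypothesis()` is the usage loop: apply a hypothesis rule set to each
profile, check consistency, tabulate verdicts and report kinds. The
four-way attribution of an inconsistency (wrong hypothesis, wrong data,
wrong representation, wrong theory) is the researcher's judgement; the
summary supports it and deliberately does not automate it.

## The synthetic generator

No raw study data is available for this instrument battery, so the
generator (`generate_cohort()`) emulates it with ground truth: qualitative
trait levels with numeric responses back-generated inside the matching
cut-point bin on two personality inventories (numeric realism — factor
structure, reliability — is explicitly not attempted, since the
toolkit's contract is qualitative); state/trait anxiety, depression and
alexithymia screens; a discrete emotion coupled to a manikin coordinate
(the coupling probability controls whether the coordinate lands in the
emotion's expected quadrant, with components sampled away from the
midpoint); free-text tokens drawn from lexicon surface forms for the
generated states; and pre/during event streams with a planted habitual
pattern (5 occurrences at a 2-day period, strictly above the default
thresholds) and, at the change rate, a planted opposing omission.
Cross-instrument contradictions are planted on extraversion at
non-adjacent levels; when the sampled level is Medium (no non-adjacent
partner exists) the planted level is resampled to Low or High and
recorded as such in the ground truth.

What passing recovery tests shows — and what it does not: with a
deterministic lexicon and above-threshold patterns, planted categories,
contradictions and changes are recovered at 100% by construction. This
validates the pipeline's bookkeeping end to end; it says nothing about
recovery on real free text (synonymy, typos, multiword answers) or on
noisy event streams near the thresholds, which is exactly why the
thresholds are surfaced rather than tuned.

Default problem sizes: unit tests run cohorts of 4–60 persons; the
end-to-end recovery suite uses 200 persons, and the randomized
rule-engine equivalence suite uses 100 random small profiles — sizes at
which the naive restart-scan oracle is still exact and fast. All
randomness flows from a single configured seed, and every output artifact
embeds an FNV-1a hash of the configuration that produced it.

## Serialization

Turtle is the canonical serialization: human-diffable, deterministic
triple order. Wave and provenance annotations are carried by baseline
RDF 1.1 reification (no RDF-star), one `rdf:Statement` node per
assertion, alongside the direct person-to-object triple; imports read the
reified nodes, so the assertion multiset round-trips exactly, including
the two `hasAffect` statements. The parser accepts exactly this dialect
(one triple per line, `@prefix` headers); OWL/XML import is out of scope.

## Known limitations

* No OWL 2 DL semantics: no complex class expressions, property chains or
  tableau reasoning — subsumption is DAG reachability, which is all the
  schema requires.
* The rule language is v1 positive-conjunctive: no negation-as-failure,
  no numeric built-ins, no weights or correlation magnitudes.
* Two waves only; longer longitudinal designs need a different wave model.
* Token lookup only: no embeddings or sentence parsing; multiword answers
  are assumed comma-separable.
* Characteristic adaptations (e.g. body image) are treated as wave-tagged
  like states; whether they should be wave-invariant is left open by the
  source material.
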