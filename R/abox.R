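# Person profiles (A-Box): assertion sets plus behavior event streams.
# Assertions are kept in a flat data frame — one row per fact — with wave
# ("pre" vs "during" the pandemic-related disruption) and provenance
# ("input", "inferred", "preset") annotations. Conflicting input values are
# stored, never overwritten: the consistency checker reports them.

ASSERTION_COLS <- c("relation", "range", "object_kind", "object", "value",
                    "valence", "arousal", "wave", "provenance", "rule_id")

empty_assertions <- function() {
  data.frame(
    relation = character(0), range = character(0),
    object_kind = character(0), object = character(0), value = character(0),
    valence = numeric(0), arousal = numeric(0),
    wave = character(0), provenance = character(0), rule_id = character(0),
    stringsAsFactors = FALSE
  )
}

empty_events <- function() {
  data.frame(
    behavior = character(0), day = numeric(0), polarity = character(0),
    value = character(0), wave = character(0), stringsAsFactors = FALSE
  )
}

#' Create an empty person profile
#'
#' @param id person identifier.
#' @return an object of class `person_profile` holding an empty assertion
#'   set and an empty behavior event stream.
#' @export
person_profile <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, assertions = empty_assertions(),
                 events = empty_events()),
            class = "person_profile")
}

#' Construct a valence/arousal coordinate
#'
#' The pictorial valence/arousal instrument reports two components on a
#' bounded scale (default 1-9); an optional radius carries intensity.
#'
#' @param valence,arousal numeric components within `bounds`.
#' @param radius optional numeric.
#' @param bounds length-2 numeric scale bounds.
#' @return an object of class `cco_coordinate`.
#' @export
coordinate <- function(valence, arousal, radius = NULL, bounds = c(1, 9)) {
  stopifnot(is.numeric(valence), is.numeric(arousal), length(bounds) == 2L)
  if (valence < bounds[1] || valence > bounds[2] ||
      arousal < bounds[1] || arousal > bounds[2]) {
    stop_psychonto(
      sprintf("coordinate (%s, %s) outside scale bounds [%s, %s]",
              valence, arousal, bounds[1], bounds[2]),
      "psychonto_range_error")
  }
  structure(list(valence = valence, arousal = arousal, radius = radius,
                 bounds = bounds),
            class = "cco_coordinate")
}

#' Add an assertion to a profile
#'
#' Validates the object against the relation's declared range(s), then
#' appends the fact. Duplicate facts are ignored (idempotent). A second
#' input value on a functional relation in the same wave is stored as a
#' pending inconsistency for [check_consistency()] to report, not rejected:
#' under open-world semantics conflicting inputs are evidence to inspect.
#'
#' @param profile a `person_profile`.
#' @param schema a `cco_schema`.
#' @param relation relation name.
#' @param object a concept label/id, a `cco_coordinate`, or a literal string
#'   for text/date-ranged relations.
#' @param wave `"pre"` or `"during"`.
#' @param provenance `"input"`, `"inferred"` or `"preset"`.
#' @param value optional qualitative payload (e.g. a level name for a
#'   concept without a level vocabulary).
#' @param rule_id id of the producing rule; required when
#'   `provenance = "inferred"`.
#' @return the updated profile.
#' @export
assert_fact <- function(profile, schema, relation, object,
                        wave = "during", provenance = "input",
                        value = NA_character_, rule_id = NA_character_) {
  stopifnot(inherits(profile, "person_profile"), inherits(schema, "cco_schema"))
  wave <- match.arg(wave, c("pre", "during"))
  provenance <- match.arg(provenance, c("input", "inferred", "preset"))
  if (provenance == "inferred" && is.na(rule_id)) {
    stop_psychonto("inferred assertions must carry the producing rule id",
                   "psychonto_assertion_error")
  }
  defs <- get_relations(schema, relation)
  row <- NULL
  if (inherits(object, "cco_coordinate")) {
    def <- Filter(function(d) d$range_kind == "coordinate", defs)
    if (length(def) == 0L) {
      stop_psychonto(sprintf("relation '%s' has no coordinate range", relation),
                     "psychonto_assertion_error")
    }
    def <- def[[1]]
    row <- data.frame(
      relation = def$name, range = def$range, object_kind = "coordinate",
      object = sprintf("%g,%g", object$valence, object$arousal),
      value = value, valence = object$valence, arousal = object$arousal,
      wave = wave, provenance = provenance, rule_id = rule_id,
      stringsAsFactors = FALSE)
  } else {
    stopifnot(is.character(object), length(object) == 1L)
    concept_defs <- Filter(function(d) d$range_kind == "concept", defs)
    cid <- tryCatch(resolve_concept(schema, object), error = function(e) NULL)
    if (!is.null(cid) && length(concept_defs)) {
      ok <- Filter(function(d) is_subclass_of(schema, cid, d$range), concept_defs)
      if (length(ok) == 0L) {
        stop_psychonto(
          sprintf("object '%s' is not a subclass of the range of '%s'",
                  object, relation),
          "psychonto_assertion_error")
      }
      def <- ok[[1]]
      row <- data.frame(
        relation = def$name, range = def$range, object_kind = "concept",
        object = cid, value = value, valence = NA_real_, arousal = NA_real_,
        wave = wave, provenance = provenance, rule_id = rule_id,
        stringsAsFactors = FALSE)
    } else {
      lit_defs <- Filter(function(d) d$range_kind %in% c("text", "date"), defs)
      if (length(lit_defs) == 0L) {
        stop_psychonto(
          sprintf("object '%s' does not conform to any range of '%s'",
                  object, relation),
          "psychonto_assertion_error")
      }
      def <- lit_defs[[1]]
      row <- data.frame(
        relation = def$name, range = def$range_kind, object_kind = def$range_kind,
        object = object, value = value, valence = NA_real_, arousal = NA_real_,
        wave = wave, provenance = provenance, rule_id = rule_id,
        stringsAsFactors = FALSE)
    }
  }
  a <- profile$assertions
  dup <- nrow(a) > 0 && any(
    a$relation == row$relation & a$range == row$range &
    a$object == row$object &
    (is.na(a$value) & is.na(row$value) |
       !is.na(a$value) & !is.na(row$value) & a$value == row$value) &
    a$wave == row$wave & a$provenance == row$provenance
  )
  if (!dup) profile$assertions <- rbind(a, row)
  profile
}

#' Query a profile's assertions
#'
#' @param profile a `person_profile`.
#' @param schema a `cco_schema`.
#' @param relation optional relation-name filter.
#' @param ancestor optional concept filter: keep assertions whose object is
#'   a subclass of this concept.
#' @param wave optional wave filter.
#' @return assertion data frame in insertion order.
#' @examples
#' s <- core_schema()
#' p <- person_profile("p1")
#' p <- assert_fact(p, s, "hasMoodProcess", "Anxious Mood")
#' nrow(query_assertions(p, s, ancestor = "Affective Process"))
#' @export
query_assertions <- function(profile, schema, relation = NULL,
                             ancestor = NULL, wave = NULL) {
  stopifnot(inherits(profile, "person_profile"))
  a <- profile$assertions
  if (!is.null(relation)) {
    get_relations(schema, relation)  # errors on unknown filter
    keep <- norm_name(a$relation) == norm_name(relation)
    a <- a[keep, , drop = FALSE]
  }
  if (!is.null(ancestor)) {
    aid <- resolve_concept(schema, ancestor)
    keep <- a$object_kind == "concept" &
      vapply(a$object, function(o) is_subclass_of(schema, o, aid), NA)
    a <- a[keep, , drop = FALSE]
  }
  if (!is.null(wave)) a <- a[a$wave == wave, , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Add a behavior event to a profile
#'
#' @param profile a `person_profile`.
#' @param schema a `cco_schema`.
#' @param behavior concept label/id under Behavior.
#' @param day non-negative day index.
#' @param polarity `"performed"` or `"omitted"` (an omitted-but-scheduled
#'   act, e.g. a skipped assignment, is itself an event).
#' @param wave `"pre"` or `"during"`.
#' @param value optional qualitative payload.
#' @return the updated profile.
#' @export
add_event <- function(profile, schema, behavior, day,
                      polarity = "performed", wave = "during",
                      value = NA_character_) {
  stopifnot(inherits(profile, "person_profile"), day >= 0)
  polarity <- match.arg(polarity, c("performed", "omitted"))
  wave <- match.arg(wave, c("pre", "during"))
  bid <- resolve_concept(schema, behavior)
  if (!is_subclass_of(schema, bid, "cco:behavior")) {
    stop_psychonto(sprintf("'%s' is not a Behavior concept", behavior),
                   "psychonto_assertion_error")
  }
  profile$events <- rbind(profile$events, data.frame(
    behavior = bid, day = as.numeric(day), polarity = polarity,
    value = value, wave = wave, stringsAsFactors = FALSE))
  profile
}

#' @export
print.person_profile <- function(x, ...) {
  cat(sprintf("<person_profile> %s: %d assertions (%d inferred), %d events\n",
              x$id, nrow(x$assertions),
              sum(x$assertions$provenance == "inferred"), nrow(x$events)))
  invisible(x)
}
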