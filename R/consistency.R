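# Constraint checking (R-Box) and the hypothesis-vs-dataset loop.
#
# Open-world: absence of a value is never an inconsistency. Reports are
# replayable — each one cites the assertions and the literal constraint
# violated.

level_rank <- function(schema, cid) {
  # position of a concept inside its level vocabulary; NA when not a level
  for (base in names(schema$constraints$level_vocab)) {
    vocab <- schema$constraints$level_vocab[[base]]
    hit <- match(cid, vocab)
    if (!is.na(hit)) return(list(base = base, rank = hit, size = length(vocab)))
  }
  NULL
}

levels_conflict <- function(schema, a, b, tolerance = 1L) {
  # two qualitative levels on the same base concept conflict when they are
  # farther apart than the adjacency tolerance; two-level vocabularies
  # (poor/good) conflict on any distinct pair
  la <- level_rank(schema, a); lb <- level_rank(schema, b)
  if (is.null(la) || is.null(lb) || la$base != lb$base) return(FALSE)
  if (la$rank == lb$rank) return(FALSE)
  if (la$size == 2L) return(TRUE)
  abs(la$rank - lb$rank) > tolerance
}

report <- function(kind, explanation, assertions) {
  structure(list(kind = kind, explanation = explanation,
                 assertions = assertions),
            class = "cco_inconsistency")
}

#' Check a profile against the schema constraints
#'
#' Detects, per wave: two distinct input values on a functional relation
#' (functional-clash); disjoint qualitative levels asserted on one concept
#' from two inputs, e.g. two instruments mapping the same trait to High and
#' Low (cross-instrument-conflict); a rule-inferred level contradicting an
#' input level (inference-vs-input-conflict); and assertions violating a
#' declared disjoint concept pair (disjointness-violation). An empty list
#' means consistent. Absent values are never reported — open world.
#'
#' @param profile a `person_profile`.
#' @param schema a `cco_schema`.
#' @param tolerance adjacency tolerance for level conflicts: with the
#'   default 1, High vs Low conflicts but High vs Medium does not; 0 makes
#'   any distinct pair conflict.
#' @return list of `cco_inconsistency` reports, each citing the involved
#'   assertions.
#' @export
check_consistency <- function(profile, schema, tolerance = 1L) {
  a <- profile$assertions
  out <- list()
  if (nrow(a) == 0L) return(out)
  for (w in unique(a$wave)) {
    aw <- a[a$wave == w, , drop = FALSE]
    # (a) functional clash among input values
    for (fr in schema$constraints$functional) {
      rows <- aw[aw$relation == fr & aw$provenance == "input", , drop = FALSE]
      vals <- unique(paste(rows$object, rows$value))
      if (nrow(rows) > 1L && length(vals) > 1L) {
        out[[length(out) + 1L]] <- report(
          "functional-clash",
          sprintf("functional relation %s has %d distinct input values in wave %s",
                  fr, length(vals), w),
          rows)
      }
    }
    # (b)/(c) qualitative level conflicts on a shared base concept
    conc <- aw[aw$object_kind == "concept", , drop = FALSE]
    if (nrow(conc) > 1L) {
      for (i in seq_len(nrow(conc) - 1L)) for (j in (i + 1L):nrow(conc)) {
        oi <- conc$object[i]; oj <- conc$object[j]
        if (levels_conflict(schema, oi, oj, tolerance)) {
          pi <- conc$provenance[i]; pj <- conc$provenance[j]
          kind <- if (pi == "input" && pj == "input") {
            "cross-instrument-conflict"
          } else if (any(c(pi, pj) == "input") && any(c(pi, pj) == "inferred")) {
            "inference-vs-input-conflict"
          } else {
            "disjointness-violation"
          }
          out[[length(out) + 1L]] <- report(
            kind,
            sprintf("disjoint levels %s and %s asserted on the same concept (wave %s)",
                    oi, oj, w),
            conc[c(i, j), , drop = FALSE])
        } else {
          for (p in schema$constraints$disjoint) {
            if ((is_subclass_of(schema, oi, p[1]) &&
                 is_subclass_of(schema, oj, p[2])) ||
                (is_subclass_of(schema, oi, p[2]) &&
                 is_subclass_of(schema, oj, p[1]))) {
              out[[length(out) + 1L]] <- report(
                "disjointness-violation",
                sprintf("%s and %s violate disjointness of (%s, %s) in wave %s",
                        oi, oj, p[1], p[2], w),
                conc[c(i, j), , drop = FALSE])
            }
          }
        }
      }
    }
  }
  out
}

#' Test a hypothesis rule set against a profile collection
#'
#' The usage loop for hypothesis-vs-dataset consistency: for each profile,
#' apply the hypothesis rules (from the input-provenance assertions) and run
#' [check_consistency()]. An inconsistency points at one of four options —
#' incorrect hypothesis, incorrect or inconsistent data, inconsistent
#' concept representation, or incorrect underlying theory — whose
#' attribution is the researcher's judgement; the summary tabulates verdicts
#' and report kinds to support that investigation, it does not automate it.
#'
#' @param rules hypothesis rule set (`cco_rulesets`, rule list or single
#'   rule).
#' @param profiles list of `person_profile`s.
#' @param schema a `cco_schema`.
#' @param tolerance see [check_consistency()].
#' @return list with `verdicts` (data frame: person, verdict, n_reports) and
#'   `summary` (counts per verdict and per report kind), plus the per-person
#'   `reports`.
#' @export
test_hypothesis <- function(rules, profiles, schema, tolerance = 1L) {
  if (inherits(profiles, "person_profile")) profiles <- list(profiles)
  verdicts <- list(); reports <- list()
  for (p in profiles) {
    p$assertions <- p$assertions[p$assertions$provenance != "inferred", ,
                                 drop = FALSE]
    res <- apply_rules(p, schema, rules)
    rep <- check_consistency(res$profile, schema, tolerance = tolerance)
    verdicts[[length(verdicts) + 1L]] <- data.frame(
      person = p$id,
      verdict = if (length(rep)) "inconsistent" else "consistent",
      n_reports = length(rep), stringsAsFactors = FALSE)
    reports[[p$id]] <- rep
  }
  verdicts <- do.call(rbind, verdicts)
  kinds <- table(unlist(lapply(reports, function(rs)
    vapply(rs, `[[`, "", "kind"))))
  list(
    verdicts = verdicts,
    summary = list(
      n_profiles = nrow(verdicts),
      n_consistent = sum(verdicts$verdict == "consistent"),
      n_inconsistent = sum(verdicts$verdict == "inconsistent"),
      kind_counts = as.list(kinds)
    ),
    reports = reports
  )
}

#' @export
print.cco_inconsistency <- function(x, ...) {
  cat(sprintf("<inconsistency: %s> %s\n", x$kind, x$explanation))
  invisible(x)
}
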