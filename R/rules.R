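# The `A -> C` rule language and forward-chaining engine.
#
# Rules are positive conjunctions of atoms: concept atoms C(?x) and property
# atoms R(?x, ?y), with variables (?p, ?x, ...) and constants resolved
# against the schema. Matching respects subclass closure (an assertion of a
# subclass satisfies a superclass atom) and sub-property closure. Forward
# chaining runs to fixpoint per wave; inferred assertions carry the
# producing rule id and a replayable support trace.

# -- parsing -----------------------------------------------------------------

parse_atom <- function(schema, text, pos_label) {
  m <- regmatches(text, regexec("^\\s*([^()]+?)\\s*\\(([^()]*)\\)\\s*$", text))[[1]]
  if (length(m) == 0L) {
    stop_psychonto(sprintf("malformed atom at %s: '%s'", pos_label, text),
                   "psychonto_parse_error")
  }
  pred_raw <- m[[2]]
  args_raw <- strsplit(m[[3]], ",")[[1]]
  if (length(args_raw) < 1L || length(args_raw) > 2L) {
    stop_psychonto(sprintf("atom at %s must have 1 or 2 arguments: '%s'",
                           pos_label, text), "psychonto_parse_error")
  }
  args <- lapply(args_raw, function(a) {
    a <- trimws(a)
    if (startsWith(a, "?")) {
      list(type = "var", name = norm_name(sub("^\\?", "", a)))
    } else {
      cid <- tryCatch(resolve_concept(schema, a), error = function(e) NULL)
      if (is.null(cid)) {
        stop_psychonto(sprintf("unknown constant '%s' at %s", a, pos_label),
                       "psychonto_vocabulary_error")
      }
      list(type = "const", name = cid)
    }
  })
  if (length(args) == 1L) {
    cid <- tryCatch(resolve_concept(schema, pred_raw), error = function(e) NULL)
    if (is.null(cid)) {
      stop_psychonto(sprintf("unknown concept '%s' at %s", pred_raw, pos_label),
                     "psychonto_vocabulary_error")
    }
    list(kind = "concept", predicate = cid, args = args)
  } else {
    defs <- tryCatch(get_relations(schema, pred_raw), error = function(e) NULL)
    if (is.null(defs)) {
      stop_psychonto(sprintf("unknown relation '%s' at %s", pred_raw, pos_label),
                     "psychonto_vocabulary_error")
    }
    list(kind = "property", predicate = defs[[1]]$name, args = args)
  }
}

atom_vars <- function(atoms) {
  unlist(lapply(atoms, function(a)
    vapply(Filter(function(x) x$type == "var", a$args), `[[`, "", "name")))
}

#' Parse a rule in `A -> C` syntax
#'
#' Antecedent and consequent are conjunctions of atoms joined by `^`,
#' separated by `->`. The parser is whitespace-tolerant: names may contain
#' irregular spacing (`has Sleep Hygiene`, `high Sleep Hygiene`) and the
#' arrow may be written `- >`. Constants and predicates are resolved against
#' the schema; unresolvable names raise a vocabulary error, a consequent
#' variable absent from the antecedent raises a safety error.
#'
#' @param schema a `cco_schema`.
#' @param text rule text, e.g.
#'   `"consume(?p,LightFood) ^ hasActivity(?p,ModerateActivity) -> hasSleepHygiene(?p,HighSleepHygiene)"`.
#' @param id rule id (defaults to a hash of the text).
#' @param theory theory preset tag.
#' @return an object of class `cco_rule`.
#' @export
parse_rule <- function(schema, text, id = NULL, theory = "adhoc") {
  raw <- text
  text <- sub("#.*$", "", text)
  text <- gsub("-\\s*>", "->", text)
  parts <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop_psychonto(
      sprintf("expected exactly one '->' (found %d) in: '%s'",
              length(parts) - 1L, raw),
      "psychonto_parse_error")
  }
  side_atoms <- function(side, label) {
    chunks <- strsplit(side, "^", fixed = TRUE)[[1]]
    chunks <- chunks[nzchar(trimws(chunks))]
    lapply(seq_along(chunks), function(i)
      parse_atom(schema, chunks[[i]], sprintf("%s atom %d", label, i)))
  }
  ante <- side_atoms(parts[[1]], "antecedent")
  cons <- side_atoms(parts[[2]], "consequent")
  if (length(cons) == 0L) {
    stop_psychonto("empty consequent", "psychonto_parse_error")
  }
  unbound <- setdiff(atom_vars(cons), atom_vars(ante))
  if (length(unbound)) {
    stop_psychonto(
      sprintf("unsafe rule: consequent variable(s) %s not bound in antecedent",
              paste0("?", unbound, collapse = ", ")),
      "psychonto_safety_error")
  }
  structure(list(
    id = id %||% paste0("rule-", fnv1a32(text)),
    antecedent = ante, consequent = cons,
    theory = theory, enabled = TRUE, text = raw
  ), class = "cco_rule")
}

#' Parse a rule file
#'
#' Plain text, one rule per line, `#` starts a comment.
#'
#' @param schema a `cco_schema`.
#' @param path file path.
#' @param theory theory tag applied to all rules in the file.
#' @return list of `cco_rule` objects, ids `<theory>-1`, `<theory>-2`, ...
#' @export
parse_rule_file <- function(schema, path, theory = NULL) {
  theory <- theory %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i)
    parse_rule(schema, lines[[i]], id = sprintf("%s-%d", theory, i),
               theory = theory))
}

#' Built-in theory presets
#'
#' Three shipped rule sets: `sleep-hygiene` encodes every row of the
#' sleep-hygiene practice table (seven inadequate-practice triggers of low
#' sleep hygiene, seven adequate-practice triggers of high sleep hygiene,
#' via the shipped prose-to-atom mapping table); `personality-sleep` encodes
#' the poor-sleep/personality associations (poor sleep types low
#' Conscientiousness and high Neuroticism); `bis-completion` encodes
#' behavioral-inhibition completion from extraversion and trait anxiety:
#' high extraversion implies low behavioral inhibition regardless of
#' anxiety, and high trait anxiety implies high behavioral inhibition only
#' at non-high extraversion (the dominance of the extraversion rule is
#' encoded by guarding the anxiety rule on the explicit low/medium levels,
#' keeping the fixpoint priority-free).
#'
#' @param schema a `cco_schema`.
#' @return an object of class `cco_rulesets`: named list mapping theory tag
#'   to its rule list.
#' @export
builtin_rulesets <- function(schema = core_schema()) {
  dir <- system.file("extdata", "rules", package = "psychonto")
  files <- list.files(dir, pattern = "\\.rules$", full.names = TRUE)
  out <- lapply(files, function(f) parse_rule_file(schema, f))
  names(out) <- vapply(files, function(f) sub("\\.rules$", "", basename(f)), "")
  structure(out, class = "cco_rulesets")
}

#' Enable or disable a theory preset
#'
#' Disabled presets contribute no inferences; recomputing inference from the
#' input-provenance assertions after a toggle removes exactly the assertions
#' derivable only through that preset.
#'
#' @param presets a `cco_rulesets`.
#' @param tag theory tag.
#' @param enabled logical.
#' @return the updated presets.
#' @export
toggle_theory <- function(presets, tag, enabled) {
  if (!tag %in% names(presets)) {
    stop_psychonto(sprintf("unknown theory preset '%s'", tag),
                   "psychonto_lookup_error")
  }
  presets[[tag]] <- lapply(presets[[tag]], function(r) {
    r$enabled <- enabled
    r
  })
  presets
}

enabled_rules <- function(rules) {
  if (inherits(rules, "cco_rule")) return(list(rules))
  # flatten rulesets and plain (possibly nested) lists down to cco_rule
  flat <- list()
  for (x in rules) {
    if (inherits(x, "cco_rule")) {
      flat[[length(flat) + 1L]] <- x
    } else {
      flat <- c(flat, Filter(function(r) inherits(r, "cco_rule"), x))
    }
  }
  Filter(function(r) isTRUE(r$enabled), flat)
}

# -- matching ----------------------------------------------------------------

# terms: the person individual is the string ".person"; every other term is
# a concept id (assertion objects, punned as individuals of their class)
PERSON_TERM <- ".person"

term_is_instance_of <- function(schema, term, cid) {
  if (identical(term, PERSON_TERM)) return(cid == "cco:person")
  is_subclass_of(schema, term, cid)
}

# enumerate bindings of a rule's antecedent against wave-local assertions
match_antecedent <- function(schema, atoms, assertions) {
  objs <- unique(assertions$object[assertions$object_kind == "concept"])
  extend <- function(env, support, i) {
    if (i > length(atoms)) return(list(list(env = env, support = support)))
    at <- atoms[[i]]
    out <- list()
    if (at$kind == "concept") {
      arg <- at$args[[1]]
      cands <- if (arg$type == "const") {
        list(arg$name)
      } else if (!is.null(env[[arg$name]])) {
        list(env[[arg$name]])
      } else {
        c(list(PERSON_TERM), as.list(objs))
      }
      for (t in cands) {
        if (term_is_instance_of(schema, t, at$predicate)) {
          env2 <- env
          if (arg$type == "var") env2[[arg$name]] <- t
          out <- c(out, extend(env2, support, i + 1L))
        }
      }
    } else {
      subj <- at$args[[1]]; obj <- at$args[[2]]
      preds <- vapply(assertions$relation, function(r)
        at$predicate %in% relation_ancestors(schema, r), NA)
      rows <- which(preds & assertions$object_kind == "concept")
      for (j in rows) {
        o <- assertions$object[[j]]
        # subject is always the person in this assertion model
        if (subj$type == "const") next
        if (!is.null(env[[subj$name]]) &&
            !identical(env[[subj$name]], PERSON_TERM)) next
        ok <- if (obj$type == "const") {
          is_subclass_of(schema, o, obj$name)
        } else if (!is.null(env[[obj$name]])) {
          identical(env[[obj$name]], o)
        } else TRUE
        if (!ok) next
        env2 <- env
        env2[[subj$name]] <- PERSON_TERM
        if (obj$type == "var") env2[[obj$name]] <- o
        out <- c(out, extend(env2, c(support, j), i + 1L))
      }
    }
    out
  }
  extend(list(), integer(0), 1L)
}

# instantiate a rule's consequent under one binding -> data frame of
# candidate assertions (relation, object) with a support trace
instantiate_consequent <- function(schema, rule, env, support, assertions) {
  rows <- list()
  trace <- paste(
    sprintf("%s=%s", assertions$relation[support], assertions$object[support]),
    collapse = " & ")
  for (at in rule$consequent) {
    if (at$kind == "property") {
      obj <- at$args[[2]]
      o <- if (obj$type == "const") obj$name else env[[obj$name]]
      rows[[length(rows) + 1L]] <-
        data.frame(relation = at$predicate, object = o,
                   rule_id = rule$id, support = trace,
                   stringsAsFactors = FALSE)
    } else {
      # re-typing: C(?z) where ?z is the object of property assertions adds
      # (relation, C) for every relation asserting ?z in this wave
      arg <- at$args[[1]]
      t <- if (arg$type == "const") arg$name else env[[arg$name]]
      if (identical(t, PERSON_TERM)) next
      rels <- unique(assertions$relation[
        assertions$object_kind == "concept" & assertions$object == t])
      for (r in rels) {
        def_ranges <- vapply(get_relations(schema, r), `[[`, "", "range")
        if (!any(vapply(def_ranges, function(rg)
          is_subclass_of(schema, at$predicate, rg), NA))) next
        rows[[length(rows) + 1L]] <-
          data.frame(relation = r, object = at$predicate,
                     rule_id = rule$id, support = trace,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Apply rules to a profile by forward chaining
#'
#' Runs the enabled rules to fixpoint, per wave. Inferred assertions carry
#' `provenance = "inferred"`, the producing rule id and a support trace of
#' the antecedent facts, so every derivation is replayable down to
#' input-provenance assertions. The fixpoint is independent of rule and
#' assertion order (positive conjunctive rules, no negation).
#'
#' @param profile a `person_profile`.
#' @param schema a `cco_schema`.
#' @param rules a `cco_rulesets`, a list of `cco_rule`, or a single rule.
#' @param max_iter iteration cap (divergence guard); defaults to
#'   `length(rules) * (number of constants)^2 + 10`, unreachable for
#'   positive conjunctive rules.
#' @return list with `profile` (updated) and `inferred` (data frame of
#'   newly added assertions).
#' @export
apply_rules <- function(profile, schema, rules, max_iter = NULL) {
  rules <- enabled_rules(rules)
  if (length(rules) == 0L || nrow(profile$assertions) == 0L) {
    return(list(profile = profile,
                inferred = cbind(empty_assertions(), support = character(0))))
  }
  max_iter <- max_iter %||%
    (length(rules) * (length(schema$concepts) + 1L)^2 + 10L)
  added_all <- cbind(empty_assertions(), support = character(0))
  for (w in unique(profile$assertions$wave)) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) {
        stop_psychonto("rule engine exceeded iteration cap",
                       "psychonto_divergence_error")
      }
      wave_rows <- profile$assertions[profile$assertions$wave == w, ,
                                      drop = FALSE]
      new_any <- FALSE
      for (rule in rules) {
        matches <- match_antecedent(schema, rule$antecedent, wave_rows)
        for (m in matches) {
          cand <- instantiate_consequent(schema, rule, m$env, m$support,
                                         wave_rows)
          if (is.null(cand)) next
          for (k in seq_len(nrow(cand))) {
            a <- profile$assertions
            exists <- any(a$relation == cand$relation[k] &
                            a$object == cand$object[k] & a$wave == w)
            if (exists) next
            profile <- assert_fact(profile, schema, cand$relation[k],
                                   cand$object[k], wave = w,
                                   provenance = "inferred",
                                   rule_id = cand$rule_id[k])
            row <- profile$assertions[nrow(profile$assertions), , drop = FALSE]
            row$support <- cand$support[k]
            added_all <- rbind(added_all, row)
            new_any <- TRUE
          }
        }
      }
      if (!new_any) break
    }
  }
  rownames(added_all) <- NULL
  list(profile = profile, inferred = added_all)
}

#' Complete missing values by inference
#'
#' Recomputes inference from the input/preset-provenance assertions
#' (discarding any previously inferred facts) under the enabled presets,
#' then reports which relations gained a first value and through which
#' rules — traceable, explainable completion. An inferred value that
#' contradicts an input value (disjoint qualitative levels on the same
#' relation) is kept but reported as a conflict; the input value is never
#' overwritten.
#'
#' @param profile a `person_profile`.
#' @param schema a `cco_schema`.
#' @param presets a `cco_rulesets` (or rule list).
#' @param tolerance adjacency tolerance for the conflict check, see
#'   [check_consistency()].
#' @return list with `profile`, `completed` (data frame: relation, object,
#'   wave, rule_id, support for relations that had no prior value) and
#'   `conflicts` (inference-vs-input reports).
#' @export
infer_missing <- function(profile, schema, presets, tolerance = 1L) {
  keep <- profile$assertions$provenance != "inferred"
  profile$assertions <- profile$assertions[keep, , drop = FALSE]
  before_rel <- unique(profile$assertions$relation)
  res <- apply_rules(profile, schema, presets)
  inf <- res$inferred
  completed <- if (nrow(inf)) {
    first <- !inf$relation %in% before_rel
    inf[first, c("relation", "object", "wave", "rule_id", "support"),
        drop = FALSE]
  } else {
    data.frame(relation = character(0), object = character(0),
               wave = character(0), rule_id = character(0),
               support = character(0), stringsAsFactors = FALSE)
  }
  rownames(completed) <- NULL
  reports <- check_consistency(res$profile, schema, tolerance = tolerance)
  conflicts <- Filter(function(r) r$kind == "inference-vs-input-conflict",
                      reports)
  list(profile = res$profile, completed = completed, conflicts = conflicts)
}

#' @export
print.cco_rule <- function(x, ...) {
  cat(sprintf("<cco_rule %s [%s]%s> %s\n", x$id, x$theory,
              if (x$enabled) "" else " (disabled)", trimws(x$text)))
  invisible(x)
}
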