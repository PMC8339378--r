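# Independent oracles. Each recomputes a quantity by a different route than
# the implementation it checks.

# exhaustive transitive closure of the subclass relation via igraph
# reachability; returns a logical matrix closure[child, ancestor]
closure_oracle <- function(schema) {
  ids <- names(schema$concepts)
  edges <- do.call(rbind, lapply(schema$concepts, function(co) {
    if (length(co$parents) == 0L) return(NULL)
    cbind(co$id, co$parents)
  }))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = TRUE, vertices = ids)
  d <- igraph::distances(g, mode = "out")
  is.finite(d)[ids, ids]
}

# brute-force binning: linear scan over cut-points (upper bin on ties)
bin_oracle <- function(value, cuts) {
  b <- 1L
  for (cut in cuts) if (value >= cut) b <- b + 1L
  b
}

# the behavioral-inhibition completion enumeration derived from the two
# correlational statements: high extraversion forces low inhibition
# regardless of anxiety; otherwise high anxiety forces high inhibition;
# otherwise nothing is concluded
bis_oracle <- function(extraversion, anxiety) {
  if (extraversion == "High") return("Low")
  if (anxiety == "High") return("High")
  NA_character_
}

# naive restart-scan forward chaining over ground rules: facts are
# (relation, object) pairs; every iteration re-grounds all rules over the
# current constant universe and scans until no fact is added
naive_fixpoint <- function(schema, facts, rules) {
  rules <- Filter(function(r) isTRUE(r$enabled),
                  if (inherits(rules, "cco_rule")) list(rules)
                  else unlist(unname(lapply(rules, function(x)
                    if (inherits(x, "cco_rule")) list(x) else x)),
                    recursive = FALSE))
  rel_anc <- function(r) {
    out <- r
    repeat {
      par <- get_relations(schema, r)[[1]]$parent
      if (is.null(par)) break
      out <- c(out, par); r <- par
    }
    out
  }
  sat_ground <- function(atom, theta, facts) {
    if (atom$kind == "concept") {
      t <- theta[[atom$args[[1]]$name]] %||% atom$args[[1]]$name
      if (identical(t, ".p")) return(atom$predicate == "cco:person")
      return(is_subclass_of(schema, t, atom$predicate))
    }
    obj <- atom$args[[2]]
    o <- if (obj$type == "const") obj$name else theta[[obj$name]]
    for (f in facts) {
      rels <- rel_anc(f[[1]])
      if (!atom$predicate %in% rels) next
      hit <- if (obj$type == "const") {
        is_subclass_of(schema, f[[2]], o)
      } else {
        identical(f[[2]], o)
      }
      if (hit) return(TRUE)
    }
    FALSE
  }
  key <- function(f) paste(f[[1]], f[[2]])
  repeat {
    universe <- c(".p", unique(vapply(facts, `[[`, "", 2L)))
    added <- FALSE
    for (rule in rules) {
      vars <- unique(unlist(lapply(c(rule$antecedent, rule$consequent),
        function(a) vapply(Filter(function(x) x$type == "var", a$args),
                           `[[`, "", "name"))))
      grid <- expand.grid(rep(list(universe), length(vars)),
                          stringsAsFactors = FALSE)
      if (length(vars) == 0L) grid <- data.frame(row.names = 1)
      for (gi in seq_len(nrow(grid))) {
        theta <- as.list(grid[gi, , drop = FALSE])
        names(theta) <- vars
        ok <- all(vapply(rule$antecedent, sat_ground, NA, theta, facts))
        if (!ok) next
        for (at in rule$consequent) {
          if (at$kind == "property") {
            obj <- at$args[[2]]
            o <- if (obj$type == "const") obj$name else theta[[obj$name]]
            if (identical(o, ".p")) next
            f <- list(at$predicate, o)
            if (!key(f) %in% vapply(facts, key, "")) {
              facts <- c(facts, list(f)); added <- TRUE
            }
          } else {
            t <- if (at$args[[1]]$type == "const") at$args[[1]]$name
                 else theta[[at$args[[1]]$name]]
            if (identical(t, ".p")) next
            for (f0 in facts) {
              if (!identical(f0[[2]], t)) next
              rngs <- vapply(get_relations(schema, f0[[1]]), `[[`, "", "range")
              if (!any(vapply(rngs, function(rg)
                is_subclass_of(schema, at$predicate, rg), NA))) next
              f <- list(f0[[1]], at$predicate)
              if (!key(f) %in% vapply(facts, key, "")) {
                facts <- c(facts, list(f)); added <- TRUE
              }
            }
          }
        }
      }
    }
    if (!added) break
  }
  sort(vapply(facts, key, ""))
}

# facts-as-pairs view of a profile's concept assertions (one wave)
profile_facts <- function(profile) {
  a <- profile$assertions
  a <- a[a$object_kind == "concept", , drop = FALSE]
  lapply(seq_len(nrow(a)), function(i) list(a$relation[i], a$object[i]))
}

fixpoint_keys <- function(profile) {
  sort(vapply(profile_facts(profile), function(f) paste(f[[1]], f[[2]]), ""))
}
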