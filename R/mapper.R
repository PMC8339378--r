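# Lexicon-driven categorization: free-text marker tokens and instrument
# responses become ontology assertions. Every token yields exactly one of
# {mapped assertion, unmapped, ambiguous} — never a silent drop.

normalize_token <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Load a lexicon
#'
#' Reads lexicon entries (surface forms, target concept, relation, frame,
#' priority, literal-vs-concept flag) plus the valence-sign table from YAML.
#' With no path, loads the shipped seed lexicon, which covers all tokens and
#' affect concepts of the core schema.
#'
#' @param path YAML file; `NULL` for the shipped seed lexicon.
#' @param schema schema used to validate targets and relations.
#' @return an object of class `cco_lexicon`.
#' @export
load_lexicon <- function(path = NULL, schema = core_schema()) {
  path <- path %||% system.file("extdata", "lexicon.yaml", package = "psychonto")
  raw <- yaml::read_yaml(path)
  entries <- lapply(raw$entries, function(e) {
    target <- resolve_concept(schema, e$target)
    defs <- get_relations(schema, e$relation)
    cdefs <- Filter(function(d) d$range_kind == "concept", defs)
    ok <- any(vapply(cdefs, function(d)
      is_subclass_of(schema, target, d$range), NA))
    if (!ok) {
      stop_psychonto(
        sprintf("lexicon target '%s' outside range of '%s'", e$target, e$relation),
        "psychonto_schema_integrity_error")
    }
    list(
      surface = vapply(e$surface, normalize_token, ""),
      target = target, relation = e$relation,
      frame = e$frame %||% "unconstrained",
      as_value = isTRUE(e$as_value),
      priority = e$priority %||% 0L
    )
  })
  signs <- vapply(raw$valence_signs %||% list(), identity, "")
  if (length(signs)) names(signs) <- vapply(names(signs), function(l)
    resolve_concept(schema, l), "")
  structure(list(entries = entries, valence_signs = signs),
            class = "cco_lexicon")
}

#' Categorize a single free-text token
#'
#' Looks the normalized token up in the lexicon under the given reporting
#' frame. The object's superclass chain determines the reported category:
#' the target's direct superclass for concept-valued entries, the target
#' class itself when the token is stored as a literal value on it.
#'
#' @param schema a `cco_schema`.
#' @param lexicon a `cco_lexicon`.
#' @param token raw token text.
#' @param frame `"feeling-report"`, `"trait-report"` or `"unconstrained"`.
#' @return a list with `status` (`mapped`, `unmapped` or `ambiguous`),
#'   `token`, and for mapped tokens `relation`, `object`, `value`,
#'   `category`; ambiguous results list the candidate targets.
#' @examples
#' s <- core_schema(); lx <- load_lexicon(schema = s)
#' categorize_token(s, lx, "bad", "feeling-report")$category
#' @export
categorize_token <- function(schema, lexicon, token,
                             frame = "unconstrained") {
  frame <- match.arg(frame, c("feeling-report", "trait-report", "unconstrained"))
  tok <- normalize_token(token)
  if (!nzchar(tok)) {
    return(list(status = "unmapped", token = token))
  }
  hits <- Filter(function(e) {
    tok %in% e$surface &&
      (e$frame == "unconstrained" || frame == "unconstrained" ||
         e$frame == frame)
  }, lexicon$entries)
  if (length(hits) == 0L) {
    return(list(status = "unmapped", token = token))
  }
  if (length(hits) > 1L) {
    pr <- vapply(hits, `[[`, 0L, "priority")
    hits <- hits[pr == max(pr)]
    if (length(hits) > 1L) {
      return(list(status = "ambiguous", token = token,
                  candidates = vapply(hits, `[[`, "", "target")))
    }
  }
  e <- hits[[1]]
  category <- if (e$as_value) {
    e$target
  } else {
    schema$concepts[[e$target]]$parents[[1]]
  }
  list(status = "mapped", token = token, relation = e$relation,
       object = e$target,
       value = if (e$as_value) tok else NA_character_,
       category = category,
       category_label = schema$concepts[[category]]$label)
}

# comma/semicolon tokenization of a free-text feeling report; leading
# conjunctions ("and fat") are stripped
tokenize_report <- function(text) {
  toks <- unlist(strsplit(text, "[,;]"))
  toks <- sub("^\\s*(and|or)\\s+", "", trimws(toks), ignore.case = TRUE)
  toks[nzchar(toks)]
}

#' Categorize a free-text record into a profile fragment
#'
#' Applies [categorize_token()] to every token and aggregates: mapped tokens
#' become assertions on a fresh (or supplied) profile; the summary counts
#' distinct categories; unmapped and ambiguous tokens are listed, never
#' dropped.
#'
#' @param schema a `cco_schema`.
#' @param lexicon a `cco_lexicon`.
#' @param tokens character vector of tokens, or a single free-text string
#'   (split on commas/semicolons).
#' @param frame reporting frame, see [categorize_token()].
#' @param profile optional existing profile to extend.
#' @param wave wave tag for the created assertions.
#' @return list with `profile`, `results` (per-token outcomes), `categories`
#'   (distinct category ids), `n_categories`, `unmapped`, `ambiguous`.
#' @examples
#' s <- core_schema(); lx <- load_lexicon(schema = s)
#' r <- categorize_record(s, lx, "bad, introverted, anxious, pain, and fat",
#'                        frame = "feeling-report")
#' r$n_categories  # 5
#' @export
categorize_record <- function(schema, lexicon, tokens,
                              frame = "unconstrained",
                              profile = NULL, wave = "during") {
  if (length(tokens) == 1L && grepl("[,;]", tokens)) {
    tokens <- tokenize_report(tokens)
  }
  profile <- profile %||% person_profile("anonymous")
  results <- lapply(tokens, function(tk)
    categorize_token(schema, lexicon, tk, frame))
  for (r in results) {
    if (r$status == "mapped") {
      profile <- assert_fact(profile, schema, r$relation, r$object,
                             wave = wave, value = r$value)
    }
  }
  mapped <- Filter(function(r) r$status == "mapped", results)
  categories <- unique(vapply(mapped, `[[`, "", "category"))
  list(
    profile = profile,
    results = results,
    categories = categories,
    category_labels = vapply(categories, function(c)
      schema$concepts[[c]]$label, ""),
    n_categories = length(categories),
    unmapped = vapply(Filter(function(r) r$status == "unmapped", results),
                      `[[`, "", "token"),
    ambiguous = vapply(Filter(function(r) r$status == "ambiguous", results),
                       `[[`, "", "token")
  )
}

# -- instrument codebooks ----------------------------------------------------

default_bins <- function(schema, target, scale) {
  # tertile cut-points onto the target's level vocabulary when one exists
  vocab <- schema$constraints$level_vocab[[target]]
  if (is.null(vocab)) return(NULL)
  k <- length(vocab)
  cuts <- scale[1] + (seq_len(k - 1) / k) * (scale[2] - scale[1])
  list(cuts = cuts, objects = vocab, values = rep(NA_character_, k))
}

#' Load instrument codebooks
#'
#' A codebook declares, per instrument and scale, the scale bounds, the
#' target relation/concept, and the score-to-qualitative-level cut-points
#' (defaulting to scale tertiles onto the Low/Medium/High vocabulary of the
#' target, where one exists). With no path, the shipped codebooks covering
#' the instrument battery (Big Five, PHQ-2, STAI state/trait, TAS-20,
#' valence/arousal manikin, behavior items) are loaded.
#'
#' @param path YAML file; `NULL` for the shipped codebooks.
#' @param schema schema used to resolve targets.
#' @return an object of class `cco_codebook` (named list of instruments).
#' @export
load_codebooks <- function(path = NULL, schema = core_schema()) {
  path <- path %||% system.file("extdata", "codebooks.yaml", package = "psychonto")
  raw <- yaml::read_yaml(path)
  out <- list()
  for (iname in names(raw$instruments)) {
    inst <- raw$instruments[[iname]]
    scale <- as.numeric(inst$scale)
    scales <- list()
    for (sname in names(inst$scales)) {
      sc <- inst$scales[[sname]]
      sscale <- if (!is.null(sc$scale)) as.numeric(sc$scale) else scale
      target <- if (!is.null(sc$target)) resolve_concept(schema, sc$target) else NULL
      bins <- if (!is.null(sc$bins)) {
        list(
          cuts = as.numeric(sc$cuts),
          objects = vapply(sc$bins, function(b)
            resolve_concept(schema, b$concept), ""),
          values = vapply(sc$bins, function(b)
            b$value %||% NA_character_, "")
        )
      } else if (!is.null(target)) {
        default_bins(schema, target, sscale) %||%
          list(cuts = sscale[1] + (1:2) / 3 * (sscale[2] - sscale[1]),
               objects = rep(target, 3),
               values = c("low", "medium", "high"))
      }
      if (!is.null(bins) && length(bins$cuts) != length(bins$objects) - 1L) {
        stop_psychonto(
          sprintf("codebook %s/%s: cut-points do not partition the scale",
                  iname, sname),
          "psychonto_codebook_error")
      }
      scales[[sname]] <- list(relation = sc$relation, target = target,
                              scale = sscale, bins = bins,
                              coordinate = isTRUE(sc$coordinate))
    }
    out[[iname]] <- list(scale = scale, scales = scales)
  }
  structure(out, class = "cco_codebook")
}

#' Map one instrument response to an assertion specification
#'
#' Discretizes a numeric score by the codebook's cut-points into a
#' qualitative object (values on a cut fall into the upper bin); coordinate
#' scales (the valence/arousal manikin) produce a coordinate object.
#'
#' @param schema a `cco_schema`.
#' @param codebook a `cco_codebook`.
#' @param instrument instrument id, e.g. `"BigFive"`.
#' @param scale_id scale id within the instrument, e.g. `"extraversion"`.
#' @param value numeric score within the scale bounds; for coordinate scales
#'   a named vector `c(valence = , arousal = )`.
#' @return list with `relation`, `object` (concept id or `cco_coordinate`)
#'   and `value` — feed to [assert_fact()].
#' @export
map_instrument_response <- function(schema, codebook, instrument, scale_id,
                                    value) {
  inst <- codebook[[instrument]]
  if (is.null(inst)) {
    stop_psychonto(sprintf("unknown instrument '%s'", instrument),
                   "psychonto_codebook_error")
  }
  sc <- inst$scales[[scale_id]]
  if (is.null(sc)) {
    stop_psychonto(sprintf("unknown scale '%s' in '%s'", scale_id, instrument),
                   "psychonto_codebook_error")
  }
  if (sc$coordinate) {
    v <- value[["valence"]]; a <- value[["arousal"]]
    return(list(relation = sc$relation,
                object = coordinate(v, a, bounds = sc$scale),
                value = NA_character_))
  }
  stopifnot(is.numeric(value), length(value) == 1L)
  if (value < sc$scale[1] || value > sc$scale[2]) {
    stop_psychonto(
      sprintf("value %s outside scale [%s, %s] for %s/%s", value,
              sc$scale[1], sc$scale[2], instrument, scale_id),
      "psychonto_range_error")
  }
  bin <- sum(value >= sc$bins$cuts) + 1L
  list(relation = sc$relation, object = sc$bins$objects[[bin]],
       value = sc$bins$values[[bin]])
}

# -- affect cross-validation -------------------------------------------------

#' Default emotion-to-quadrant expectations
#'
#' Circumplex placements (valence sign, arousal band) for the discrete
#' emotions and moods of the core schema, used to cross-validate discrete
#' emotion reports against valence/arousal coordinates.
#'
#' @return data frame with columns `concept`, `valence`, `arousal`.
#' @export
default_quadrant_table <- function() {
  data.frame(
    concept = c("cco:amusement", "cco:anger", "cco:anxiety", "cco:boredom",
                "cco:compassion", "cco:anxious-mood", "cco:cheerful-mood",
                "cco:gloomy-mood"),
    valence = c("pos", "neg", "neg", "neg", "pos", "neg", "pos", "neg"),
    arousal = c("high", "high", "high", "low", "low", "high", "high", "low"),
    stringsAsFactors = FALSE
  )
}

#' Cross-validate discrete and coordinate affect reports
#'
#' The dual affect representation stores a discrete emotion and a
#' valence/arousal coordinate side by side. For every same-wave pair this
#' maps the coordinate to its quadrant (split at the scale midpoint; a
#' component exactly on the midpoint matches either side) and compares it
#' with the discrete emotion's expected quadrant. Disagreements flag
#' potential reporting biases.
#'
#' @param profile a `person_profile`.
#' @param schema a `cco_schema`.
#' @param quadrant_table expectation table, see [default_quadrant_table()].
#' @param bounds coordinate scale bounds (default 1-9).
#' @return list with `status` (`"ok"` or `"not-applicable"`) and `pairs`, a
#'   data frame with one row per (discrete, coordinate) same-wave pair and
#'   an `agree` flag.
#' @export
cross_validate_affect <- function(profile, schema,
                                  quadrant_table = default_quadrant_table(),
                                  bounds = c(1, 9)) {
  a <- profile$assertions
  coords <- a[a$object_kind == "coordinate", , drop = FALSE]
  disc <- a[a$object_kind == "concept" &
              a$object %in% quadrant_table$concept, , drop = FALSE]
  if (nrow(coords) == 0L || nrow(disc) == 0L ||
      !any(coords$wave %in% disc$wave)) {
    return(list(status = "not-applicable",
                pairs = data.frame()))
  }
  mid <- mean(bounds)
  side <- function(x, hi, lo) if (x > mid) hi else if (x < mid) lo else "mid"
  rows <- list()
  for (w in intersect(unique(coords$wave), unique(disc$wave))) {
    for (i in which(disc$wave == w)) for (j in which(coords$wave == w)) {
      exp_row <- quadrant_table[quadrant_table$concept == disc$object[i], ]
      ov <- side(coords$valence[j], "pos", "neg")
      oa <- side(coords$arousal[j], "high", "low")
      agree <- (ov == "mid" || ov == exp_row$valence) &&
               (oa == "mid" || oa == exp_row$arousal)
      rows[[length(rows) + 1L]] <- data.frame(
        wave = w, emotion = disc$object[i],
        valence = coords$valence[j], arousal = coords$arousal[j],
        expected_valence = exp_row$valence, expected_arousal = exp_row$arousal,
        agree = agree, stringsAsFactors = FALSE)
    }
  }
  list(status = "ok", pairs = do.call(rbind, rows))
}
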