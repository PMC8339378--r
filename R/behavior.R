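# Behavior-stream semantics: singular vs habitual classification,
# cross-wave behavior change, and well-being summarization.

#' Classify a behavior event stream as singular or habitual
#'
#' A behavior is habitual when it repeats over a specific time span or
#' periodically in a specific pattern: here, when some contiguous sub-span
#' of the events holds at least `k` occurrences whose best-period slot-fill
#' fraction reaches `r` (candidate periods are capped at `span / k` so that
#' a claimed period leaves at least `k` repetition opportunities).
#' Otherwise the events are singular — stand-alone occurrences. Scoring a
#' sub-span rather than the whole window makes the label monotone: adding
#' an occurrence can never turn a habitual stream singular.
#'
#' @param events event data frame (columns `behavior`, `day`, `polarity`,
#'   `value`, `wave`) for a single behavior concept.
#' @param window observation window in days (events outside are ignored
#'   when a `window` is given as `c(first, last)`; a single number means
#'   days `0 .. window - 1`).
#' @param k habitual support threshold (default 3 occurrences).
#' @param r regularity threshold: minimum fraction of periodic slots filled
#'   (default 0.6).
#' @return a `pattern_label` list: `behavior`, `label`
#'   (`"singular"`/`"habitual"`/`"none"`), `support`, `span`,
#'   `periodicity`.
#' @export
classify_frequency <- function(events, window = 14, k = 3, r = 0.6) {
  stopifnot(k >= 1, r >= 0, r <= 1)
  if (length(window) == 1L) window <- c(0, window - 1)
  ev <- events[events$day >= window[1] & events$day <= window[2], ,
               drop = FALSE]
  if (nrow(ev) == 0L) {
    return(structure(list(behavior = unique(events$behavior) %||% NA_character_,
                          label = "none", support = 0L, span = 0,
                          periodicity = 0), class = "pattern_label"))
  }
  beh <- unique(ev$behavior)
  if (length(beh) != 1L) {
    stop_psychonto("classify_frequency expects events of a single behavior",
                   "psychonto_assertion_error")
  }
  days <- sort(unique(ev$day))
  best <- 0
  habitual <- FALSE
  for (i in seq_along(days)) for (j in i:length(days)) {
    sub <- days[days >= days[i] & days <= days[j]]
    if (length(sub) < k) next
    span <- days[j] - days[i] + 1
    for (p in seq_len(max(1L, floor(span / k)))) {
      slots <- ceiling(span / p)
      filled <- length(unique(floor((sub - days[i]) / p)))
      frac <- filled / slots
      if (frac > best) best <- frac
      if (frac >= r) habitual <- TRUE
    }
  }
  structure(list(
    behavior = beh,
    label = if (habitual) "habitual" else "singular",
    support = nrow(ev), span = max(days) - min(days) + 1,
    periodicity = best
  ), class = "pattern_label")
}

dominant <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[[1]]
}

#' Detect behavior change across waves
#'
#' Compares the pre-wave and during-wave streams of one behavior. A change
#' is emitted when (a) a during-wave singular event opposes an established
#' pre-wave habitual pattern — opposite polarity or a different qualitative
#' value on the same behavior — or (b) both waves are habitual but the
#' dominant polarity or value shifted. A pre-wave singular behavior is
#' never evidence of change, and with no pre-wave data the stream is judged
#' with only the available information: no change, insufficiency noted.
#'
#' @param events event data frame for one behavior across both waves.
#' @param window,k,r thresholds passed to [classify_frequency()]; the
#'   window applies within each wave's own day numbering.
#' @return a `change_report` list: `behavior`, `change` (logical), `type`
#'   (`"singular-opposition"`, `"habitual-shift"` or `"none"`), `note`, and
#'   the two wave labels.
#' @export
detect_change <- function(events, window = 14, k = 3, r = 0.6) {
  beh <- unique(events$behavior)
  pre <- events[events$wave == "pre", , drop = FALSE]
  dur <- events[events$wave == "during", , drop = FALSE]
  mk <- function(change, type, note, pre_lab, dur_lab) {
    structure(list(behavior = if (length(beh)) beh[[1]] else NA_character_,
                   change = change, type = type, note = note,
                   pre = pre_lab, dur = dur_lab),
              class = "change_report")
  }
  if (nrow(pre) == 0L) {
    dl <- if (nrow(dur)) classify_frequency(dur, window, k, r) else NULL
    return(mk(FALSE, "none",
              "no pre-wave data: judged with only the available information",
              NULL, dl))
  }
  pre_lab <- classify_frequency(pre, window, k, r)
  dur_lab <- if (nrow(dur)) classify_frequency(dur, window, k, r) else NULL
  if (pre_lab$label != "habitual") {
    # a previous singular behavior cannot ground a change judgement
    return(mk(FALSE, "none", "pre-wave behavior is singular, not an established pattern",
              pre_lab, dur_lab))
  }
  pre_pol <- dominant(pre$polarity)
  pre_val <- dominant(pre$value)
  if (is.null(dur_lab) || nrow(dur) == 0L) {
    return(mk(FALSE, "none", "no during-wave data", pre_lab, dur_lab))
  }
  opposes <- dur$polarity != pre_pol |
    (!is.na(dur$value) & !is.na(pre_val) & dur$value != pre_val)
  if (dur_lab$label == "habitual") {
    dur_pol <- dominant(dur$polarity)
    dur_val <- dominant(dur$value)
    shifted <- !identical(dur_pol, pre_pol) ||
      (!is.na(dur_val) && !is.na(pre_val) && dur_val != pre_val)
    if (shifted) {
      return(mk(TRUE, "habitual-shift",
                "during-wave habitual pattern differs from pre-wave pattern",
                pre_lab, dur_lab))
    }
    if (any(opposes)) {
      return(mk(TRUE, "singular-opposition",
                "event opposing the established pre-wave pattern",
                pre_lab, dur_lab))
    }
    return(mk(FALSE, "none", "patterns identical across waves", pre_lab, dur_lab))
  }
  if (any(opposes)) {
    return(mk(TRUE, "singular-opposition",
              "singular during-wave event opposes the established pre-wave pattern",
              pre_lab, dur_lab))
  }
  mk(FALSE, "none", "during-wave events consistent with pre-wave pattern",
     pre_lab, dur_lab)
}

#' Detect changes for every behavior in a profile
#'
#' @param profile a `person_profile` with event streams.
#' @param window,k,r see [detect_change()].
#' @return list of `change_report`s, one per behavior concept present.
#' @export
detect_changes <- function(profile, window = 14, k = 3, r = 0.6) {
  ev <- profile$events
  lapply(split(ev, ev$behavior), detect_change, window = window, k = k, r = r)
}

#' Summarize emotional and physical well-being
#'
#' Emotional well-being rolls up affect-family assertions (affective
#' processes, appraisals, physiological responses to emotion) by valence
#' sign; physical well-being rolls up its building blocks — nutrition,
#' physical activity and sleep (including rule-inferred sleep hygiene).
#' Every component lists its contributing assertions; components with no
#' evidence are reported as unknown, never defaulted.
#'
#' @param profile a `person_profile`.
#' @param schema a `cco_schema`.
#' @param lexicon a `cco_lexicon` carrying the valence-sign table.
#' @return list with `emotional` (`n_positive`, `n_negative`, `verdict`,
#'   `contributions`) and `physical` (per-component status and verdict).
#' @export
evaluate_wellbeing <- function(profile, schema, lexicon = load_lexicon(schema = schema)) {
  a <- profile$assertions
  conc <- a[a$object_kind == "concept", , drop = FALSE]
  # emotional: affect-family objects with a valence sign
  fam <- conc[vapply(conc$object, function(o)
    is_subclass_of(schema, o, "cco:mental-emotional-functioning"), NA), ,
    drop = FALSE]
  # a screen scoring an affect concept at the "low" level is not evidence of
  # that affect; only present/medium/high-level assertions contribute
  fam <- fam[is.na(fam$value) | fam$value != "low", , drop = FALSE]
  signs <- lexicon$valence_signs[fam$object]
  emo <- list(
    n_positive = sum(signs == "positive", na.rm = TRUE),
    n_negative = sum(signs == "negative", na.rm = TRUE),
    contributions = cbind(fam, sign = unname(signs))
  )
  emo$verdict <- if (nrow(fam) == 0L) "unknown"
    else if (emo$n_negative == 0L) "favorable"
    else if (emo$n_positive == 0L) "unfavorable"
    else "mixed"
  # physical: nutrition / activity / sleep components
  favorable <- c("cco:balanced-diet", "cco:regular-exercise",
                 "cco:moderate-activity", "cco:high-sleep-hygiene",
                 "cco:high-sleep-quality", "cco:good-sleep",
                 "cco:adequate-sleep-duration", "cco:regular-wake-time")
  unfavorable <- c("cco:poor-diet", "cco:low-sleep-hygiene",
                   "cco:low-sleep-quality", "cco:poor-sleep",
                   "cco:irregular-sleep-schedule")
  comp_roots <- c(nutrition = "cco:food-diet", activity = "cco:exercise",
                  sleep = "cco:sleep")
  comp_extra <- list(
    nutrition = c("cco:food", "cco:consumption-behavior"),
    activity = "cco:activity",
    sleep = c("cco:sleep-hygiene", "cco:sleep-quality", "cco:sleep-behavior",
              "cco:sleepiness", "cco:chronotype")
  )
  physical <- list()
  for (cn in names(comp_roots)) {
    roots <- c(comp_roots[[cn]], comp_extra[[cn]])
    rows <- conc[vapply(conc$object, function(o)
      any(vapply(roots, function(rt) is_subclass_of(schema, o, rt), NA)), NA), ,
      drop = FALSE]
    status <- if (nrow(rows) == 0L) "unknown"
      else if (any(rows$object %in% unfavorable)) "unfavorable"
      else if (any(rows$object %in% favorable)) "favorable"
      else "present"
    physical[[cn]] <- list(status = status, contributions = rows)
  }
  known <- vapply(physical, function(x) x$status, "")
  physical$verdict <- if (all(known == "unknown")) "unknown" else
    sprintf("favorable on %d/%d components",
            sum(known == "favorable"), length(known))
  list(emotional = emo, physical = physical)
}
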