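# Configuration, survey/event-stream readers, and provenance hashing.

CONFIG_KEYS <- c("lexicon", "codebooks", "presets", "window", "k", "r",
                 "tolerance", "coupling", "inconsistency_rate", "change_rate",
                 "habit_support", "habit_period", "n", "seed")

default_config <- function() {
  list(
    lexicon = NULL, codebooks = NULL,
    presets = c("sleep-hygiene", "personality-sleep", "bis-completion"),
    window = 14, k = 3, r = 0.6, tolerance = 1,
    coupling = 0.9, inconsistency_rate = 0.1, change_rate = 0.3,
    habit_support = 5, habit_period = 2,
    n = 50, seed = 1
  )
}

#' Load a run configuration
#'
#' YAML keys override the defaults; unknown keys are rejected (schema
#' validation before any run).
#'
#' @param path optional YAML file.
#' @return named configuration list with a `hash` attribute used to stamp
#'   output artifacts.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), CONFIG_KEYS)
    if (length(bad)) {
      stop_psychonto(sprintf("unknown config key(s): %s",
                             paste(bad, collapse = ", ")),
                     "psychonto_config_error")
    }
    cfg[names(user)] <- user
  }
  stopifnot(cfg$k >= 1, cfg$r >= 0, cfg$r <= 1, cfg$window > 0,
            cfg$coupling >= 0, cfg$coupling <= 1,
            cfg$inconsistency_rate >= 0, cfg$inconsistency_rate <= 1,
            cfg$change_rate >= 0, cfg$change_rate <= 1, cfg$n >= 1)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Provenance hash of a configuration
#'
#' @param cfg configuration list.
#' @return 8-character hexadecimal hash.
#' @export
config_hash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  fnv1a32(paste(deparse(cfg[order(names(cfg))]), collapse = ""))
}

#' Read a wide-format survey export into person profiles
#'
#' One row per person. Columns named `<Instrument>.<scale>` (matching the
#' codebook, e.g. `BigFive.extraversion`) are discretized through
#' [map_instrument_response()]; the paired `SAM.valence`/`SAM.arousal`
#' columns become one coordinate assertion; a `tokens` column (semicolon-
#' separated free text) is categorized through the lexicon; a `gender`
#' column maps to `hasGender`. `person` identifies the row, `wave`
#' (optional) tags the assertions.
#'
#' @param x path to a delimited file (CSV) or a data frame.
#' @param schema a `cco_schema`.
#' @param codebooks a `cco_codebook`.
#' @param lexicon a `cco_lexicon`.
#' @param frame reporting frame for the tokens column.
#' @return named list of `person_profile`s, plus a `"categorization"`
#'   attribute with the per-person token outcomes.
#' @export
read_survey <- function(x, schema, codebooks, lexicon,
                        frame = "feeling-report") {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE, check.names = FALSE) else x
  stopifnot("person" %in% names(df))
  profiles <- list()
  catinfo <- list()
  inst_cols <- grep("\\.", names(df), value = TRUE)
  for (i in seq_len(nrow(df))) {
    pid <- as.character(df$person[i])
    wave <- if ("wave" %in% names(df)) df$wave[i] else "during"
    prof <- person_profile(pid)
    if ("gender" %in% names(df) && !is.na(df$gender[i])) {
      prof <- assert_fact(prof, schema, "hasGender", df$gender[i], wave = wave)
    }
    sam <- c(valence = NA_real_, arousal = NA_real_)
    for (col in inst_cols) {
      val <- df[[col]][i]
      if (is.na(val)) next
      parts <- strsplit(col, ".", fixed = TRUE)[[1]]
      instr <- parts[1]; scale_id <- parts[2]
      if (instr == "SAM") {
        sam[[scale_id]] <- as.numeric(val)
        next
      }
      resp <- map_instrument_response(schema, codebooks, instr, scale_id,
                                      as.numeric(val))
      prof <- assert_fact(prof, schema, resp$relation, resp$object,
                          wave = wave, value = resp$value)
    }
    if (!any(is.na(sam))) {
      resp <- map_instrument_response(schema, codebooks, "SAM", "affect", sam)
      prof <- assert_fact(prof, schema, resp$relation, resp$object, wave = wave)
    }
    if ("tokens" %in% names(df) && !is.na(df$tokens[i]) &&
        nzchar(df$tokens[i])) {
      toks <- trimws(strsplit(df$tokens[i], ";")[[1]])
      res <- categorize_record(schema, lexicon, toks, frame = frame,
                               profile = prof, wave = wave)
      prof <- res$profile
      catinfo[[pid]] <- res
    }
    profiles[[pid]] <- prof
  }
  attr(profiles, "categorization") <- catinfo
  profiles
}

#' Read a long-format behavior event stream
#'
#' Columns: `person`, `behavior`, `day`, `polarity`, `value`, `wave`.
#'
#' @param x path to a delimited file (CSV) or a data frame.
#' @param profiles named list of profiles to attach events to; persons not
#'   present are created.
#' @param schema a `cco_schema`.
#' @return the updated profile list.
#' @export
read_events <- function(x, profiles, schema) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE, check.names = FALSE) else x
  for (i in seq_len(nrow(df))) {
    pid <- as.character(df$person[i])
    if (is.null(profiles[[pid]])) profiles[[pid]] <- person_profile(pid)
    profiles[[pid]] <- add_event(
      profiles[[pid]], schema, df$behavior[i], df$day[i],
      polarity = df$polarity[i], wave = df$wave[i],
      value = if ("value" %in% names(df)) as.character(df$value[i])
              else NA_character_)
  }
  profiles
}
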