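# Synthetic cohort generator emulating the study's instrument battery, with
# ground-truth labels for every planted category, contradiction and
# behavior change. All stochastic choices flow from one seed.

#' Generator parameters
#'
#' @param n number of persons (>= 1).
#' @param seed integer RNG seed.
#' @param trait_dist probabilities of the Low/Medium/High trait levels.
#' @param coupling probability that a generated discrete emotion's
#'   valence/arousal coordinate lands in its expected quadrant.
#' @param inconsistency_rate probability of planting a cross-instrument
#'   trait contradiction in a person.
#' @param change_rate probability of planting a behavior change between the
#'   waves of a person's event stream.
#' @param habit_support occurrences in a planted habitual pattern (kept
#'   above the default habitual threshold so planted patterns are
#'   recoverable).
#' @param habit_period day gap between pattern occurrences.
#' @return validated parameter list of class `generator_params`.
#' @export
generator_params <- function(n = 50, seed = 1,
                             trait_dist = c(1, 1, 1) / 3,
                             coupling = 0.9,
                             inconsistency_rate = 0.1,
                             change_rate = 0.3,
                             habit_support = 5, habit_period = 2) {
  stopifnot(n >= 1, length(trait_dist) == 3, all(trait_dist >= 0),
            abs(sum(trait_dist) - 1) < 1e-8,
            coupling >= 0, coupling <= 1,
            inconsistency_rate >= 0, inconsistency_rate <= 1,
            change_rate >= 0, change_rate <= 1,
            habit_support >= 1, habit_period >= 1)
  structure(as.list(environment()), class = "generator_params")
}

# numeric response inside the bin of a given level index (1-based), away
# from the cut boundaries
sample_in_bin <- function(scale, cuts, bin) {
  lo <- if (bin == 1L) scale[1] else cuts[bin - 1L]
  hi <- if (bin > length(cuts)) scale[2] else cuts[bin]
  eps <- (hi - lo) * 0.05
  stats::runif(1, lo + eps, hi - eps)
}

#' Generate a synthetic survey cohort with ground truth
#'
#' For each person: qualitative trait levels with numeric instrument
#' responses back-generated inside the matching cut-point bin (two
#' personality inventories, state/trait anxiety, depression screen,
#' alexithymia); a discrete emotion from the schema's emotion inventory
#' with a valence/arousal coordinate coupled to its expected quadrant; free-
#' text tokens drawn from lexicon surface forms for the generated states;
#' pre/during behavior event streams with a planted habitual pattern and,
#' at the change rate, a planted opposing change; and, at the inconsistency
#' rate, a planted cross-instrument trait contradiction. The ground truth
#' records everything planted.
#'
#' @param params a [generator_params()] list.
#' @param schema a `cco_schema`.
#' @param lexicon a `cco_lexicon`; generation fails if it lacks a surface
#'   form for a state it needs to verbalize (a lexicon gap).
#' @param codebooks a `cco_codebook`.
#' @param dir optional output directory; when given, writes `survey.csv`,
#'   `events.csv` and `truth.json`.
#' @return list with `survey` (wide data frame), `events` (long data
#'   frame), `truth` (per-person list) and `params`.
#' @export
generate_cohort <- function(params = generator_params(),
                            schema = core_schema(),
                            lexicon = load_lexicon(schema = schema),
                            codebooks = load_codebooks(schema = schema),
                            dir = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(params$seed)

  levels3 <- c("Low", "Medium", "High")
  traits5 <- c("openness", "conscientiousness", "extraversion",
               "agreeableness", "neuroticism")
  emotions <- c("cco:amusement", "cco:anger", "cco:anxiety", "cco:boredom",
                "cco:compassion")
  qt <- default_quadrant_table()

  # reverse lexicon: concept id -> a surface form usable in a feeling report
  surface_for <- function(cid) {
    for (e in lexicon$entries) {
      if (e$target == cid && !e$as_value &&
          e$frame %in% c("feeling-report", "unconstrained")) {
        return(e$surface[[1]])
      }
    }
    stop_psychonto(sprintf("lexicon has no feeling-report surface for '%s'", cid),
                   "psychonto_generation_error")
  }
  feelings <- c("cco:feeling-bad", "cco:feeling-calm", "cco:feeling-alert",
                "cco:feeling-at-ease")
  bodily <- c("cco:hunger", "cco:pain", "cco:thirst", "cco:physical-pleasure")

  survey <- list(); events <- list(); truth <- list()
  for (i in seq_len(params$n)) {
    pid <- sprintf("p%03d", i)
    tr <- list()
    row <- list(person = pid, wave = "during",
                gender = sample(c("female", "male", "diverse"), 1))
    # five-factor traits on two inventories, trait anxiety, screens
    for (t in traits5) {
      lv <- sample(levels3, 1, prob = params$trait_dist)
      tr[[t]] <- lv
      sc <- codebooks[["BigFive"]]$scales[[t]]
      row[[paste0("BigFive.", t)]] <-
        round(sample_in_bin(sc$scale, sc$bins$cuts, match(lv, levels3)), 3)
    }
    contradiction <- stats::runif(1) < params$inconsistency_rate
    if (contradiction && tr$extraversion == "Medium") {
      # a non-adjacent contradiction needs a non-central planted level
      tr$extraversion <- sample(c("Low", "High"), 1)
      sc <- codebooks[["BigFive"]]$scales$extraversion
      row[["BigFive.extraversion"]] <-
        round(sample_in_bin(sc$scale, sc$bins$cuts,
                            match(tr$extraversion, levels3)), 3)
    }
    for (t in traits5) {
      lv <- tr[[t]]
      if (contradiction && t == "extraversion") {
        lv <- if (tr$extraversion == "High") "Low" else "High"
      }
      sc <- codebooks[["BigFive-alt"]]$scales[[t]]
      row[[paste0("BigFive-alt.", t)]] <-
        round(sample_in_bin(sc$scale, sc$bins$cuts, match(lv, levels3)), 3)
    }
    tr$trait_anxiety <- sample(levels3, 1, prob = params$trait_dist)
    sc <- codebooks[["STAI-trait"]]$scales$trait_anxiety
    row[["STAI-trait.trait_anxiety"]] <-
      round(sample_in_bin(sc$scale, sc$bins$cuts,
                          match(tr$trait_anxiety, levels3)), 3)
    for (spec in list(c("STAI-state", "state_anxiety"),
                      c("PHQ-2", "depression"),
                      c("TAS-20", "alexithymia"))) {
      lv <- sample(levels3, 1)
      sc <- codebooks[[spec[1]]]$scales[[spec[2]]]
      row[[paste(spec[1], spec[2], sep = ".")]] <-
        round(sample_in_bin(sc$scale, sc$bins$cuts, match(lv, levels3)), 3)
    }
    # discrete emotion + coupled coordinate
    emo <- sample(emotions, 1)
    exp_q <- qt[qt$concept == emo, ]
    in_quadrant <- stats::runif(1) < params$coupling
    vside <- if (in_quadrant) exp_q$valence else
      ifelse(exp_q$valence == "pos", "neg", "pos")
    aside <- if (in_quadrant) exp_q$arousal else
      ifelse(exp_q$arousal == "high", "low", "high")
    row[["SAM.valence"]] <- round(if (vside == "pos")
      stats::runif(1, 5.5, 9) else stats::runif(1, 1, 4.5), 2)
    row[["SAM.arousal"]] <- round(if (aside == "high")
      stats::runif(1, 5.5, 9) else stats::runif(1, 1, 4.5), 2)
    # free-text feeling report: feeling + bodily + emotion surfaces
    feel <- sample(feelings, 1); bod <- sample(bodily, 1)
    toks <- c(surface_for(feel), surface_for(bod), surface_for(emo))
    row[["tokens"]] <- paste(toks, collapse = ";")
    planted_cats <- c(
      schema$concepts[[feel]]$parents[[1]],
      schema$concepts[[bod]]$parents[[1]],
      schema$concepts[[emo]]$parents[[1]]
    )
    # behavior streams: planted habitual pattern, optional planted change
    habit_days <- seq(0, by = params$habit_period,
                      length.out = params$habit_support)
    beh <- "cco:learning-task"
    ev <- data.frame(person = pid, behavior = beh, day = habit_days,
                     polarity = "performed", value = NA_character_,
                     wave = "pre", stringsAsFactors = FALSE)
    change <- stats::runif(1) < params$change_rate
    ev_dur <- if (change) {
      data.frame(person = pid, behavior = beh,
                 day = habit_days[ceiling(length(habit_days) / 2)],
                 polarity = "omitted", value = NA_character_,
                 wave = "during", stringsAsFactors = FALSE)
    } else {
      transform(ev, wave = "during")
    }
    events[[pid]] <- rbind(ev, ev_dur)
    survey[[pid]] <- row
    truth[[pid]] <- list(
      traits = tr,
      emotion = emo,
      coordinate_in_expected_quadrant = in_quadrant,
      tokens = toks,
      categories = planted_cats,
      contradiction = contradiction,
      contradiction_trait = if (contradiction) "extraversion" else NULL,
      change = change,
      change_behavior = if (change) beh else NULL
    )
  }
  survey <- do.call(rbind, lapply(survey, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  rownames(survey) <- NULL
  events <- do.call(rbind, events)
  rownames(events) <- NULL
  out <- list(survey = survey, events = events, truth = truth,
              params = params)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(survey, file.path(dir, "survey.csv"), row.names = FALSE)
    utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
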