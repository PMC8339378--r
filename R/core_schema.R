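# The shipped core schema: upper-level class hierarchy, the mental emotional
# functioning expansion, the person-to-factor relation inventory, qualitative
# level vocabularies and the rule-trigger vocabulary used by the built-in
# rule presets.

#' Build the core psychological concept schema
#'
#' Constructs the shipped T-Box/R-Box: the upper-level classes (Person,
#' Character, Behavior, Situation, Coordinate, Culture, Food, Well-Being,
#' Disease, plus Country referenced by the demographic relations), the
#' mental-emotional-functioning expansion (affective processes, appraisals,
#' physiological responses), the personality cluster (five-factor traits plus
#' Trait Anxiety and the behavioral activation/inhibition pair), the relation
#' inventory mapping uncategorized input to the factor hierarchy (including
#' the deliberately duplicated `hasAffect` with both a discrete affective
#' process range and a valence/arousal coordinate range), qualitative
#' Low/Medium/High level vocabularies for traits and sleep hygiene/quality,
#' and the behavior vocabulary the built-in sleep-hygiene rules match on.
#'
#' @return a validated `cco_schema`.
#' @examples
#' s <- core_schema()
#' length(direct_subclasses(s, "Character"))  # 3 clusters
#' @export
core_schema <- function() {
  s <- ontology_schema()

  ## ---- upper-level classes ----
  s <- add_concept(s, "Person", factor = "general")
  s <- add_concept(s, "Character", factor = "character")
  s <- add_concept(s, "Behavior", factor = "behavior")
  s <- add_concept(s, "Situation", factor = "situation")
  s <- add_concept(s, "Coordinate", source = "emoca", factor = "character")
  s <- add_concept(s, "Culture", factor = "general")
  s <- add_concept(s, "Food", source = "helis", factor = "behavior")
  s <- add_concept(s, "Well-Being", factor = "character")
  s <- add_concept(s, "Disease", factor = "character")
  # range of the country-of-origin/residence demographic relations
  s <- add_concept(s, "Country", factor = "general")

  ## ---- character: three subclass clusters ----
  s <- add_concept(s, "Characteristic Adaptation", "Character")
  for (x in c("Appearance", "Body Image", "Goal", "Motivation"))
    s <- add_concept(s, x, "Characteristic Adaptation")

  s <- add_concept(s, "Mental Emotional Functioning", "Character",
                   source = "emotions-onto")
  s <- add_concept(s, "Affective Process", "Mental Emotional Functioning",
                   source = "emotions-onto")
  s <- add_concept(s, "Appraisal", "Mental Emotional Functioning",
                   source = "emotions-onto")
  s <- add_concept(s, "Physiological Response To Emotion Process",
                   "Mental Emotional Functioning", source = "emotions-onto")
  s <- add_concept(s, "Appraisal Process", "Mental Emotional Functioning",
                   source = "emotions-onto")

  # affective process families and their enumerated members
  s <- add_concept(s, "Bodily Feeling", "Affective Process", source = "emotions-onto")
  for (x in c("Hunger", "Pain", "Thirst", "Physical Pleasure"))
    s <- add_concept(s, x, "Bodily Feeling", source = "emotions-onto")
  s <- add_concept(s, "Emotion Process", "Affective Process", source = "emotions-onto")
  for (x in c("Amusement", "Anger", "Anxiety", "Boredom", "Compassion"))
    s <- add_concept(s, x, "Emotion Process", source = "emotions-onto")
  s <- add_concept(s, "Mood Process", "Affective Process", source = "emotions-onto")
  for (x in c("Anxious Mood", "Cheerful Mood", "Gloomy Mood"))
    s <- add_concept(s, x, "Mood Process", source = "emotions-onto")
  s <- add_concept(s, "Subjective Emotional Feeling", "Affective Process",
                   source = "emotions-onto")
  for (x in c("Feeling Alert", "Feeling At Ease", "Feeling Bad", "Feeling Calm"))
    s <- add_concept(s, x, "Subjective Emotional Feeling", source = "emotions-onto")

  for (x in c("Appraisal Of Being Disliked", "Appraisal Of Being Liked",
              "Appraisal Of Avoidability Of Consequences", "Appraisal Of Loss"))
    s <- add_concept(s, x, "Appraisal", source = "emotions-onto")
  for (x in c("Becoming Pale", "Blushing", "Perspiring", "Shivering"))
    s <- add_concept(s, x, "Physiological Response To Emotion Process",
                     source = "emotions-onto")

  # personality: five-factor traits plus trait anxiety and BIS/BAS
  s <- add_concept(s, "Personality", "Character")
  ffm <- c("Openness", "Conscientiousness", "Extraversion", "Agreeableness",
           "Neuroticism")
  traits <- c(ffm, "Trait Anxiety", "Behavioral Activation",
              "Behavioral Inhibition")
  for (x in traits) s <- add_concept(s, x, "Personality")

  ## ---- behavior ----
  s <- add_concept(s, "Singular Behavior", "Behavior")
  for (x in c("Activity", "Emotional Behavioral Process", "Consumption Behavior",
              "Entertainment Behavior", "Sleep Behavior"))
    s <- add_concept(s, x, "Singular Behavior")
  s <- add_concept(s, "Habitual Behavior", "Behavior")
  for (x in c("Chronotype", "Food Diet", "Sleep", "Sleep Hygiene",
              "Sleep Quality", "Sleepiness", "Exercise"))
    s <- add_concept(s, x, "Habitual Behavior")
  s <- add_concept(s, "Learning Behavior", "Behavior", factor = "learning")
  for (x in c("Learning Frequency", "Learning Timing", "Learning Medium",
              "Learning Modality", "Learning Quality"))
    s <- add_concept(s, x, "Learning Behavior")

  ## ---- situation ----
  s <- add_concept(s, "Task", "Situation")
  for (x in c("Performed Task", "Cognitive Task", "Sleep Task"))
    s <- add_concept(s, x, "Task")
  s <- add_concept(s, "Environment", "Situation")
  s <- add_concept(s, "Social Situation", "Situation")
  s <- add_concept(s, "Learning Situation", "Situation", factor = "learning")
  # dual representation: a learning task is both a task and a behavior
  s <- add_concept(s, "Learning Task", c("Task", "Learning Behavior"),
                   source = "paper-extension")

  ## ---- coordinate, culture, food, well-being, disease ----
  s <- add_concept(s, "Component", "Coordinate", source = "emoca")
  s <- add_concept(s, "Arousal", "Component", source = "emoca")
  s <- add_concept(s, "Valence", "Component", source = "emoca")
  s <- add_concept(s, "Radius", "Coordinate", source = "emoca")
  for (x in c("Ethnic Identity", "Religion", "Nationality", "Residence"))
    s <- add_concept(s, x, "Culture")
  s <- add_concept(s, "Basic Food", "Food", source = "helis")
  s <- add_concept(s, "Nutrient", "Food", source = "helis")
  s <- add_concept(s, "Emotional Well-Being", "Well-Being")
  s <- add_concept(s, "Physical Well-Being", "Well-Being")
  s <- add_concept(s, "Sleep Disorder", "Disease")
  s <- add_concept(s, "Pathological Mental Response", "Disease")

  ## ---- qualitative level vocabularies (R-Box) ----
  for (tr in traits) s <- add_level_vocab(s, tr)
  s <- add_level_vocab(s, "Sleep Hygiene")
  s <- add_level_vocab(s, "Sleep Quality")
  s <- add_level_vocab(s, "Sleep", levels = c("Poor", "Good"))

  ## ---- rule-trigger vocabulary (sleep-hygiene mapping table targets) ----
  s <- add_concept(s, "Light Food", "Basic Food", source = "helis")
  s <- add_concept(s, "Moderate Activity", "Activity", source = "helis")
  for (x in c("Pre-Bedtime Stimulant Use", "Evening Caffeine Avoidance",
              "Pre-Bedtime Alcohol Nicotine Avoidance"))
    s <- add_concept(s, x, "Consumption Behavior", source = "paper-extension")
  for (x in c("Daytime Napping", "Non-Sleep Activity In Bed",
              "Quiet Comfortable Sleep Environment"))
    s <- add_concept(s, x, "Sleep Behavior", source = "paper-extension")
  for (x in c("Irregular Sleep Schedule", "Adequate Sleep Duration",
              "Regular Wake Time"))
    s <- add_concept(s, x, "Sleep", source = "paper-extension")
  s <- add_concept(s, "Pre-Bedtime Upsetting Event", "Emotional Behavioral Process",
                   source = "paper-extension")
  for (x in c("Pre-Bedtime High Concentration Activity",
              "Pre-Bedtime Mental Activity"))
    s <- add_concept(s, x, "Activity", source = "paper-extension")
  s <- add_concept(s, "Regular Exercise", "Exercise", source = "paper-extension")
  # diet quality values used by well-being summarization
  s <- add_concept(s, "Balanced Diet", "Food Diet", source = "paper-extension")
  s <- add_concept(s, "Poor Diet", "Food Diet", source = "paper-extension")
  s <- add_disjoint(s, "Balanced Diet", "Poor Diet")

  ## ---- relation inventory ----
  rel <- function(s, name, range, factor, functional = FALSE, parent = NULL,
                  source = "core", range_kind = "concept") {
    add_relation(s, name, range, factor, functional, parent, source, range_kind)
  }
  # general
  s <- rel(s, "hasDateOfBirth", "date", "general", functional = TRUE,
           range_kind = "date")
  s <- rel(s, "hasGender", "text", "general", functional = TRUE,
           range_kind = "text")
  s <- rel(s, "hasMaritalStatus", "text", "general", functional = TRUE,
           range_kind = "text")
  s <- rel(s, "hasCountryOfOrigin", "Country", "general", functional = TRUE)
  s <- rel(s, "hasCountryOfResidence", "Country", "general", functional = TRUE)
  s <- rel(s, "hasCulture", "Culture", "general")  # deliberately multi-valued
  # character: the dual affect representation plus per-family state relations
  s <- rel(s, "hasAffect", "Coordinate", "character", range_kind = "coordinate")
  s <- rel(s, "hasAffect", "Affective Process", "character")
  s <- rel(s, "hasBodilyFeeling", "Bodily Feeling", "character")
  s <- rel(s, "hasEmotionProcess", "Emotion Process", "character")
  s <- rel(s, "hasMoodProcess", "Mood Process", "character")
  s <- rel(s, "hasSubjEmotionalFeeling", "Subjective Emotional Feeling", "character")
  s <- rel(s, "hasAppraisal", "Appraisal", "character")
  s <- rel(s, "hasPhysiologicalResponse",
           "Physiological Response To Emotion Process", "character")
  s <- rel(s, "hasAppraisalProcess", "Appraisal Process", "character")
  s <- rel(s, "hasPersonality", "Personality", "character")
  s <- rel(s, "hasCharacteristicAdaptation", "Characteristic Adaptation",
           "character", source = "paper-extension")
  # per-trait sub-properties of hasPersonality (hierarchy-implied relations)
  trait_rel <- c(Openness = "hasOpenness",
                 Conscientiousness = "hasConscientiousness",
                 Extraversion = "hasExtraversion",
                 Agreeableness = "hasAgreeableness",
                 Neuroticism = "hasNeuroticism",
                 "Trait Anxiety" = "hasTraitAnxiety",
                 "Behavioral Activation" = "hasBehavioralActivation",
                 "Behavioral Inhibition" = "hasBehavioralInhibition")
  for (tr in names(trait_rel)) {
    s <- rel(s, trait_rel[[tr]], tr, "character", parent = "hasPersonality",
             source = "paper-extension")
  }
  # behavior
  s <- rel(s, "hasActivity", "Activity", "behavior")
  s <- rel(s, "hasEmotionalBehavioralProcess", "Emotional Behavioral Process",
           "behavior")
  s <- rel(s, "hasConsumptionBeh", "Consumption Behavior", "behavior")
  s <- rel(s, "hasEntertainmentBeh", "Entertainment Behavior", "behavior")
  s <- rel(s, "hasSleepBeh", "Sleep Behavior", "behavior")
  s <- rel(s, "hasChronotype", "Chronotype", "behavior", functional = TRUE)
  s <- rel(s, "hasFoodDiet", "Food Diet", "behavior")
  s <- rel(s, "hasSleep", "Sleep", "behavior")
  s <- rel(s, "hasSleepHygiene", "Sleep Hygiene", "behavior", functional = TRUE)
  s <- rel(s, "hasSleepQuality", "Sleep Quality", "behavior", functional = TRUE)
  s <- rel(s, "hasSleepiness", "Sleepiness", "behavior")
  s <- rel(s, "hasExercise", "Exercise", "behavior")
  s <- rel(s, "consume", "Food", "behavior", source = "helis")
  # situation
  s <- rel(s, "inEnvironment", "Environment", "situation")
  s <- rel(s, "hasTask", "Task", "situation")
  s <- rel(s, "inSocialSituation", "Social Situation", "situation")
  # learning
  s <- rel(s, "hasLearningOrientedAffect", "Mental Emotional Functioning",
           "learning")
  s <- rel(s, "hasLearningRelatedBehavior", "Learning Behavior", "learning")
  s <- rel(s, "inLearningRelatedSituation", "Learning Situation", "learning")

  validate_schema(s)
  s
}
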