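# Instrument codebooks: scale bounds and score-to-concept mappings.
# Scales without explicit bins are discretized at tertile cut-points onto
# the target's Low/Medium/High vocabulary (or carried as a literal level
# value when the target has none).
instruments:
  BigFive:
    scale: [1, 5]
    scales:
      openness:          {relation: hasOpenness,          target: Openness}
      conscientiousness: {relation: hasConscientiousness, target: Conscientiousness}
      extraversion:      {relation: hasExtraversion,      target: Extraversion}
      agreeableness:     {relation: hasAgreeableness,     target: Agreeableness}
      neuroticism:       {relation: hasNeuroticism,       target: Neuroticism}
  # second personality inventory on a different response scale; unifying it
  # with BigFive onto the common trait concepts is what enables the
  # cross-instrument consistency check
  BigFive-alt:
    scale: [0, 100]
    scales:
      openness:          {relation: hasOpenness,          target: Openness}
      conscientiousness: {relation: hasConscientiousness, target: Conscientiousness}
      extraversion:      {relation: hasExtraversion,      target: Extraversion}
      agreeableness:     {relation: hasAgreeableness,     target: Agreeableness}
      neuroticism:       {relation: hasNeuroticism,       target: Neuroticism}
  PHQ-2:
    scale: [0, 6]
    scales:
      depression: {relation: hasMoodProcess, target: Gloomy Mood}
  STAI-state:
    scale: [20, 80]
    scales:
      state_anxiety: {relation: hasMoodProcess, target: Anxious Mood}
  STAI-trait:
    scale: [20, 80]
    scales:
      trait_anxiety: {relation: hasTraitAnxiety, target: Trait Anxiety}
  TAS-20:
    scale: [20, 100]
    scales:
      alexithymia: {relation: hasAppraisalProcess, target: Appraisal Process}
  SAM:
    scale: [1, 9]
    scales:
      affect: {relation: hasAffect, coordinate: true}
  behavior-items:
    scale: [1, 9]
    scales:
      sleep_quality: {relation: hasSleepQuality, target: Sleep Quality}
      diet:
        relation: hasFoodDiet
        cuts: [5]
        bins:
          - {concept: Poor Diet}
          - {concept: Balanced Diet}
      exercise:
        relation: hasExercise
        scale: [0, 7]
        cuts: [3]
        bins:
          - {concept: Exercise, value: infrequent}
          - {concept: Regular Exercise}
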