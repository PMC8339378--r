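# Seed lexicon: free-text marker tokens -> ontology concepts.
#
# frame restricts when an entry may fire: feeling-report (describing current
# feelings), trait-report (describing stable dispositions), or unconstrained.
# as_value: true stores the token as a literal value on the target class
# (the class itself is then the reported category); otherwise the target is
# a specific concept and its direct superclass is the category.
entries:
  - surface: [bad]
    target: Feeling Bad
    relation: hasSubjEmotionalFeeling
    frame: feeling-report
  - surface: [alert]
    target: Feeling Alert
    relation: hasSubjEmotionalFeeling
    frame: feeling-report
  - surface: [at ease]
    target: Feeling At Ease
    relation: hasSubjEmotionalFeeling
    frame: feeling-report
  - surface: [calm]
    target: Feeling Calm
    relation: hasSubjEmotionalFeeling
    frame: feeling-report
  - surface: [introverted, introvert]
    target: Personality
    relation: hasPersonality
    frame: unconstrained
    as_value: true
  - surface: [extroverted, extrovert, extraverted]
    target: Personality
    relation: hasPersonality
    frame: unconstrained
    as_value: true
  - surface: [anxious]
    target: Anxious Mood
    relation: hasMoodProcess
    frame: feeling-report
  - surface: [anxious, anxiety]
    target: Trait Anxiety
    relation: hasTraitAnxiety
    frame: trait-report
  - surface: [anxiety]
    target: Anxiety
    relation: hasEmotionProcess
    frame: feeling-report
  - surface: [pain]
    target: Pain
    relation: hasBodilyFeeling
    frame: unconstrained
  - surface: [hunger, hungry]
    target: Hunger
    relation: hasBodilyFeeling
    frame: unconstrained
  - surface: [thirst, thirsty]
    target: Thirst
    relation: hasBodilyFeeling
    frame: unconstrained
  - surface: [pleasure]
    target: Physical Pleasure
    relation: hasBodilyFeeling
    frame: unconstrained
  - surface: [fat]
    target: Body Image
    relation: hasCharacteristicAdaptation
    frame: feeling-report
    as_value: true
  - surface: [amused, amusement]
    target: Amusement
    relation: hasEmotionProcess
    frame: unconstrained
  - surface: [angry, anger]
    target: Anger
    relation: hasEmotionProcess
    frame: unconstrained
  - surface: [bored, boredom]
    target: Boredom
    relation: hasEmotionProcess
    frame: unconstrained
  - surface: [compassion, compassionate]
    target: Compassion
    relation: hasEmotionProcess
    frame: unconstrained
  - surface: [cheerful]
    target: Cheerful Mood
    relation: hasMoodProcess
    frame: feeling-report
  - surface: [gloomy]
    target: Gloomy Mood
    relation: hasMoodProcess
    frame: feeling-report
  - surface: [pale]
    target: Becoming Pale
    relation: hasPhysiologicalResponse
    frame: unconstrained
  - surface: [blushing]
    target: Blushing
    relation: hasPhysiologicalResponse
    frame: unconstrained
  - surface: [perspiring, sweating]
    target: Perspiring
    relation: hasPhysiologicalResponse
    frame: unconstrained
  - surface: [shivering]
    target: Shivering
    relation: hasPhysiologicalResponse
    frame: unconstrained

# valence sign of affect-family concepts, used by emotional well-being
# roll-up (positive / negative)
valence_signs:
  Feeling Bad: negative
  Feeling Alert: positive
  Feeling At Ease: positive
  Feeling Calm: positive
  Hunger: negative
  Pain: negative
  Thirst: negative
  Physical Pleasure: positive
  Amusement: positive
  Anger: negative
  Anxiety: negative
  Boredom: negative
  Compassion: positive
  Anxious Mood: negative
  Cheerful Mood: positive
  Gloomy Mood: negative
  Becoming Pale: negative
  Blushing: negative
  Perspiring: negative
  Shivering: negative
  Appraisal Of Being Liked: positive
  Appraisal Of Being Disliked: negative
  Appraisal Of Loss: negative
  Appraisal Of Avoidability Of Consequences: positive
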