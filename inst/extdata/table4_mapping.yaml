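# Versioned mapping from the prose sleep-hygiene practice rows to machine
# atoms. The practice table gives prose descriptions, not atoms; each row is
# normalized to one (relation, trigger concept) pair, and the corresponding
# rule asserts the stated sleep-hygiene level. Row 8 is the worked
# light-snack/moderate-activity rule and carries a two-atom antecedent.
version: 1
rows:
  - row: 1
    column: inadequate
    prose: "Alcohol, tobacco, or caffeine consumption in the period preceding bedtime"
    atoms: [{relation: hasConsumptionBeh, concept: Pre-Bedtime Stimulant Use}]
    consequent: Low Sleep Hygiene
  - row: 2
    column: inadequate
    prose: "Daytime napping"
    atoms: [{relation: hasSleepBeh, concept: Daytime Napping}]
    consequent: Low Sleep Hygiene
  - row: 3
    column: inadequate
    prose: "Variable wake-up or bedtimes"
    atoms: [{relation: hasSleep, concept: Irregular Sleep Schedule}]
    consequent: Low Sleep Hygiene
  - row: 4
    column: inadequate
    prose: "Engaging in emotionally upsetting events too close to bedtime"
    atoms: [{relation: hasEmotionalBehavioralProcess, concept: Pre-Bedtime Upsetting Event}]
    consequent: Low Sleep Hygiene
  - row: 5
    column: inadequate
    prose: "Non-sleep activities (e.g., television watching, reading, studying, snacking, etc.)"
    atoms: [{relation: hasSleepBeh, concept: Non-Sleep Activity In Bed}]
    consequent: Low Sleep Hygiene
  - row: 6
    column: inadequate
    prose: "Performing activities that require high levels of concentration shortly before bedtime"
    atoms: [{relation: hasActivity, concept: Pre-Bedtime High Concentration Activity}]
    consequent: Low Sleep Hygiene
  - row: 7
    column: inadequate
    prose: "Mental activities"
    atoms: [{relation: hasActivity, concept: Pre-Bedtime Mental Activity}]
    consequent: Low Sleep Hygiene
  - row: 8
    column: adequate
    prose: "Hunger may disturb sleep, a light bedtime snack seems to help individuals to sleep"
    atoms:
      - {relation: consume, concept: Light Food}
      - {relation: hasActivity, concept: Moderate Activity}
    consequent: High Sleep Hygiene
  - row: 9
    column: adequate
    prose: "Sleeping as much as needed to feel refreshed and healthy during the following day"
    atoms: [{relation: hasSleep, concept: Adequate Sleep Duration}]
    consequent: High Sleep Hygiene
  - row: 10
    column: adequate
    prose: "Regular arousal time in the morning"
    atoms: [{relation: hasSleep, concept: Regular Wake Time}]
    consequent: High Sleep Hygiene
  - row: 11
    column: adequate
    prose: "Caffeine in the evening disturbs sleep"
    atoms: [{relation: hasConsumptionBeh, concept: Evening Caffeine Avoidance}]
    consequent: High Sleep Hygiene
  - row: 12
    column: adequate
    prose: "Avoiding Alcohol, Nicotine use before bedtime"
    atoms: [{relation: hasConsumptionBeh, concept: Pre-Bedtime Alcohol Nicotine Avoidance}]
    consequent: High Sleep Hygiene
  - row: 13
    column: adequate
    prose: "Sleeping in a quiet and comfortable environment"
    atoms: [{relation: hasSleepBeh, concept: Quiet Comfortable Sleep Environment}]
    consequent: High Sleep Hygiene
  - row: 14
    column: adequate
    prose: "Regular Exercise"
    atoms: [{relation: hasExercise, concept: Regular Exercise}]
    consequent: High Sleep Hygiene
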