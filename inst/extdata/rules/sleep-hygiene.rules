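# Sleep-hygiene evaluation rules: one rule per row of the practice table,
# normalized to machine atoms via table4_mapping.yaml.
# Inadequate practices -> low sleep hygiene
hasConsumptionBeh(?p, PreBedtimeStimulantUse) -> hasSleepHygiene(?p, LowSleepHygiene)
hasSleepBeh(?p, DaytimeNapping) -> hasSleepHygiene(?p, LowSleepHygiene)
hasSleep(?p, IrregularSleepSchedule) -> hasSleepHygiene(?p, LowSleepHygiene)
hasEmotionalBehavioralProcess(?p, PreBedtimeUpsettingEvent) -> hasSleepHygiene(?p, LowSleepHygiene)
hasSleepBeh(?p, NonSleepActivityInBed) -> hasSleepHygiene(?p, LowSleepHygiene)
hasActivity(?p, PreBedtimeHighConcentrationActivity) -> hasSleepHygiene(?p, LowSleepHygiene)
hasActivity(?p, PreBedtimeMentalActivity) -> hasSleepHygiene(?p, LowSleepHygiene)
# Adequate practices -> high sleep hygiene
consume(?p, LightFood) ^ hasActivity(?p, ModerateActivity) -> hasSleepHygiene(?p, HighSleepHygiene)
hasSleep(?p, AdequateSleepDuration) -> hasSleepHygiene(?p, HighSleepHygiene)
hasSleep(?p, RegularWakeTime) -> hasSleepHygiene(?p, HighSleepHygiene)
hasConsumptionBeh(?p, EveningCaffeineAvoidance) -> hasSleepHygiene(?p, HighSleepHygiene)
hasConsumptionBeh(?p, PreBedtimeAlcoholNicotineAvoidance) -> hasSleepHygiene(?p, HighSleepHygiene)
hasSleepBeh(?p, QuietComfortableSleepEnvironment) -> hasSleepHygiene(?p, HighSleepHygiene)
hasExercise(?p, RegularExercise) -> hasSleepHygiene(?p, HighSleepHygiene)
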