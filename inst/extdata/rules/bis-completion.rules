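# Behavioral-inhibition completion from extraversion and trait anxiety:
# (1) high extraversion implies low behavioral inhibition regardless of
# anxiety; (2) high trait anxiety implies high behavioral inhibition, but
# only at non-high extraversion (explicit level guards keep the fixpoint
# priority-free while giving rule 1 dominance).
Person(?p) ^ hasExtraversion(?p, HighExtraversion) -> hasBehavioralInhibition(?p, LowBehavioralInhibition)
Person(?p) ^ hasExtraversion(?p, LowExtraversion) ^ hasTraitAnxiety(?p, HighTraitAnxiety) -> hasBehavioralInhibition(?p, HighBehavioralInhibition)
Person(?p) ^ hasExtraversion(?p, MediumExtraversion) ^ hasTraitAnxiety(?p, HighTraitAnxiety) -> hasBehavioralInhibition(?p, HighBehavioralInhibition)
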