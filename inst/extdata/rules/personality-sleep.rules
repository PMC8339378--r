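# Personality-sleep associations: poor sleep types the person's
# conscientiousness as low and neuroticism as high (qualitative direction
# only). The conscientiousness rule is kept in its hand-written spaced form
# to exercise the whitespace-tolerant parser.
Person(?x) ^ has Sleep(?x,?y) ^ PoorSleep(?y) ^ has Conscientiousness(?x,?z) - > Low Conscientiousness(?z)
Person(?x) ^ hasSleep(?x,?y) ^ PoorSleep(?y) ^ hasNeuroticism(?x,?z) -> HighNeuroticism(?z)
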