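Mental Emotional Functioning
Affective Process
Appraisal
Physiological Response To Emotion Process
Appraisal Process
Bodily Feeling
Hunger
Pain
Thirst
Physical Pleasure
Emotion Process
Amusement
Anger
Anxiety
Boredom
Compassion
Mood Process
Anxious Mood
Cheerful Mood
Gloomy Mood
Subjective Emotional Feeling
Feeling Alert
Feeling At Ease
Feeling Bad
Feeling Calm
Appraisal Of Being Disliked
Appraisal Of Being Liked
Appraisal Of Avoidability Of Consequences
Appraisal Of Loss
Becoming Pale
Blushing
Perspiring
Shivering
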