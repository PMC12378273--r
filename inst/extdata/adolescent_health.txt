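# Adolescent-health domain vocabulary used by the keyword regularizer's
# dictionary boost. One term per line; '#' comments. Multiword entries are
# matched as adjacent-token bigrams when bigram vocabulary is enabled, else
# by either component token.
sleep
stress
depression
anxiety
nutrition
bullying
self-harm
substance
screen
cyber
mental health
wellbeing
addiction
mindfulness
exercise
suicide
therapy
meditation
resilience
counseling
psychology
social media
selfcare
trauma
emotion
diagnosis
insomnia
disorder
coping
psychotherapy
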