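# Swedish trigger lexicon, baseline profile.
# Reconstructed negation cue set: pre-negations (PREN), post-negations (POST),
# pseudo-negations (PSEU) and scope-terminating conjunctions (CONJ).
# Format: phrase<TAB>[TAG]; '#' starts a comment; matching is case-insensitive.
inga	[PREN]
ingen	[PREN]
inget	[PREN]
inte	[PREN]
ej	[PREN]
icke	[PREN]
aldrig	[PREN]
utan	[PREN]
ingenting	[PREN]
intet	[PREN]
förnekar	[PREN]
avsaknad av	[PREN]
inga tecken	[PREN]
utan tecken	[PREN]
inte visar	[PREN]
visar inte	[PREN]
har inte	[PREN]
inte har	[PREN]
hade inte	[PREN]
inte hade	[PREN]
osannolik	[POST]
osannolikt	[POST]
kan uteslutas	[POST]
uteslutet	[POST]
inte säkert om	[PSEU]
ej säkert om	[PSEU]
kan inte utesluta	[PSEU]
utan tvekan	[PSEU]
men	[CONJ]
dock	[CONJ]
förutom	[CONJ]
bortsett från	[CONJ]
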