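# Swedish trigger lexicon, refined profile.
# As the baseline set, but with the trigger "icke" removed (in clinical Swedish
# it almost always opens a disease name, e.g. "icke allergisk astma") and with
# "utan" subject to the runtime disambiguation rule: an occurrence of "utan"
# preceded by "inte" earlier in the sentence is a conjunction ("but"), not a
# negation, and is masked by the engine under this profile.
# Format: phrase<TAB>[TAG]; '#' starts a comment; matching is case-insensitive.
inga	[PREN]
ingen	[PREN]
inget	[PREN]
inte	[PREN]
ej	[PREN]
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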