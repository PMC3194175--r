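# Synthetic demonstration term list in ICD-10 export style:
# code<TAB>description, one term per line.  Descriptions carry the kinds of
# parentheticals and clarifier phrases that the term-list cleaner removes.
# This is illustrative material written for this package, not an excerpt of
# any classification release.
J45	Astma (allergisk)
J18	Pneumoni, ej specificerad
R50	Feber, ospecificerad
R05	Hosta
R23	Cyanos
R51	Huvudvärk
E14	Diabetes, ospecificerad
R42	Yrsel (och svindel)
R06	Dyspné
R11	Illamående, andra specificerade former
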