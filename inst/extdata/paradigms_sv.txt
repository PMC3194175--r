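# Default Swedish suffix-rule inflection paradigms for trigger expansion.
# Sections: [adjective], [verb], [overrides].
# Rule lines: suffix-pattern<TAB>replacement1,replacement2,...
#   - the first rule whose suffix-pattern ends the lemma wins;
#   - an empty pattern (line starting with a TAB) is the catch-all;
#   - an empty replacement reproduces the lemma stem unchanged.
# Override lines ([overrides]): lemma<TAB>form1,form2,... define a closed
# inflection group; expanding any member yields the whole group.
[adjective]
t	t,ta
	,t,a
[verb]
a	a,ar,ade,at

[overrides]
ha	har,hade,haft
se	ser,såg,sett
kunna	kan,kunde,kunnat
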