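super_population	tier	individuals	carriers
AFR	unfiltered	661	0
AMR	unfiltered	347	3
EAS	unfiltered	504	1
EUR	unfiltered	503	12
SAS	unfiltered	489	9
AFR	coverage_340	561	0
AMR	coverage_340	300	3
EAS	coverage_340	413	0
EUR	coverage_340	360	10
SAS	coverage_340	468	9
AFR	coverage_780	548	0
AMR	coverage_780	279	3
EAS	coverage_780	332	0
EUR	coverage_780	272	7
SAS	coverage_780	468	9
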