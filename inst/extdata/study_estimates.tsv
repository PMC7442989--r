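study	carriers	n	beta	se
GCKD	74	4771	-13.0	3.6
KORA_F3	56	3099	-12.6	3.5
KORA_F4	63	3040	-9.9	3.1
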