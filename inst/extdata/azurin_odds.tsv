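seq_id	group	category	probability	odds
azurin	F	Cell_envelope	0.5923	9.71
azurin	EZ	Nonenzyme	0.8144	1.147
azurin	GO	Immune_response	0.4995	5.877
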