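condition	start_ms	end_ms
snare	0	1376100
hihat	1376100	1405800
syllable	1405800	1752300
none	1752300	1980000
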