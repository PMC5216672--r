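Begin Time (s)	End Time (s)	Low Freq (Hz)	High Freq (Hz)	frog_id	overlapped
1.204	1.488	1050	3900	F001	FALSE
4.731	5.012	1020	3850	F001	FALSE
8.290	8.571	1050	3900	F001	TRUE
12.115	12.402	1100	4050	F002	FALSE
15.880	16.163	1080	4000	F002	FALSE
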