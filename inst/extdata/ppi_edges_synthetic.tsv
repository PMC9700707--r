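protein_a	protein_b	combined_score
PCSK9	HMGCR	950
PCSK9	MTTP	905
PCSK9	APOC3	987
PCSK9	LPA	920
PCSK9	CETP	966
PCSK9	APOB	999
HMGCR	MTTP	941
HMGCR	APOC3	972
HMGCR	LPA	810
HMGCR	CETP	745
HMGCR	APOB	880
MTTP	APOC3	702
MTTP	LPA	766
MTTP	CETP	834
MTTP	APOB	512
APOC3	LPA	455
APOC3	CETP	620
APOC3	APOB	401
LPA	CETP	588
LPA	APOB	433
CETP	APOB	210
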