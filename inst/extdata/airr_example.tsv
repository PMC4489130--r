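sequence_id	junction_aa	duplicate_count	productive
seq1	CARWDYW	12	T
seq2	CARWDYW	3	T
seq3	CAKLGGYFDYW	6	T
seq4	CAR	10	T
seq5	CARDYFDLW	1	T
seq6	CTTVPQGW	4	F
seq7	CARSSGYW	2	T
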