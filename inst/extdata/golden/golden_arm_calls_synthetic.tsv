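sample_id	arm	cutoff	call
S1	1p	0.1	GAIN
S1	1q	0.1	LOSS
S1	2p	0.1	NEUTRAL
S2	1p	0.1	NO_CALL
S2	1q	0.1	GAIN
S3	2p	0.1	LOSS
S4	1p	0.1	GAIN
S4	1q	0.1	NO_CALL
S5	1p	0.1	GAIN
S5	1q	0.1	LOSS
S5	2p	0.1	GAIN
S6	2q	0.1	LOSS
S6	3p	0.1	NO_CALL
S7	1p	0.1	GAIN
S7	1q	0.1	GAIN
S7	2p	0.1	GAIN
S7	2q	0.1	GAIN
S8	1p	0.1	GAIN
S1	1p	0.2	GAIN
S1	1q	0.2	LOSS
S1	2p	0.2	NEUTRAL
S2	1p	0.2	NO_CALL
S2	1q	0.2	GAIN
S3	2p	0.2	LOSS
S4	1p	0.2	GAIN
S4	1q	0.2	NO_CALL
S5	1p	0.2	GAIN
S5	1q	0.2	NEUTRAL
S5	2p	0.2	NEUTRAL
S6	2q	0.2	LOSS
S6	3p	0.2	NO_CALL
S7	1p	0.2	NEUTRAL
S7	1q	0.2	NEUTRAL
S7	2p	0.2	NEUTRAL
S7	2q	0.2	NEUTRAL
S8	1p	0.2	GAIN
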