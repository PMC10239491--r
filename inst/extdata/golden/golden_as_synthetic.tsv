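sample_id	cutoff	n_altered	n_evaluable	as_score
S1	0.1	2	3	0.666666666666667
S2	0.1	1	2	0.5
S3	0.1	1	1	1
S4	0.1	1	2	0.5
S5	0.1	3	3	1
S6	0.1	1	2	0.5
S7	0.1	4	4	1
S8	0.1	1	1	1
S1	0.2	2	3	0.666666666666667
S2	0.2	1	2	0.5
S3	0.2	1	1	1
S4	0.2	1	2	0.5
S5	0.2	1	3	0.333333333333333
S6	0.2	1	2	0.5
S7	0.2	0	4	0
S8	0.2	1	1	1
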