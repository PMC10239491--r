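ID	chrom	loc.start	loc.end	num.mark	seg.mean
S1	1	1	121535434	NA	0.45
S1	1	124535435	249250621	NA	-0.38
S1	2	1	92326171	NA	0.02
S2	1	1	72921260	NA	0.5
S2	1	72921261	121535434	NA	0
S2	1	124535435	249250621	NA	0.3
S3	1	1	36460630	NA	0.6
S3	2	1	69244628	NA	-0.5
S4	1	1	174421509	NA	0.35
S4	1	174421510	249250621	NA	0
S5	1	1	121535434	NA	0.2
S5	1	124535435	249250621	NA	-0.1
S5	2	1	92326171	NA	0.15
S6	3	1	45252427	NA	0.4
S6	3	45252428	90504854	NA	-0.4
S6	2	95326172	213624733	NA	-0.25
S6	2	213624734	243199373	NA	0.25
S7	1	1	121535434	NA	0.15
S7	1	124535435	249250621	NA	0.15
S7	2	1	92326171	NA	0.15
S7	2	95326172	243199373	NA	0.15
S8	1	1	12153543	NA	0.3
S8	1	12153544	24307087	NA	0.3
S8	1	24307088	36460630	NA	0.3
S8	1	36460631	48614174	NA	0.3
S8	1	48614175	60767717	NA	0.3
S8	1	60767718	72921260	NA	0.3
S8	1	72921261	85074804	NA	0.3
S8	1	85074805	97228347	NA	0.3
S8	1	97228348	109381891	NA	0
S8	1	109381892	121535434	NA	0
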