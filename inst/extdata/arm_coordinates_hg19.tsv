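arm	chrom	start	end
1p	1	1	121535434
1q	1	124535435	249250621
2p	2	1	92326171
2q	2	95326172	243199373
3p	3	1	90504854
3q	3	93504855	198022430
4p	4	1	49660117
4q	4	52660118	191154276
5p	5	1	46405641
5q	5	49405642	180915260
6p	6	1	58830166
6q	6	61830167	171115067
7p	7	1	58054331
7q	7	61054332	159138663
8p	8	1	43838887
8q	8	46838888	146364022
9p	9	1	47367679
9q	9	50367680	141213431
10p	10	1	39254935
10q	10	42254936	135534747
11p	11	1	51644205
11q	11	54644206	135006516
12p	12	1	34856694
12q	12	37856695	133851895
13q	13	19000001	115169878
14q	14	19000001	107349540
15q	15	20000001	102531392
16p	16	1	35335801
16q	16	38335802	90354753
17p	17	1	22263006
17q	17	25263007	81195210
18p	18	1	15460898
18q	18	18460899	78077248
19p	19	1	24681782
19q	19	27681783	59128983
20p	20	1	26369569
20q	20	29369570	63025520
21q	21	14288130	48129895
22q	22	16000001	51304566
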