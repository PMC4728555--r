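position	pos_A	pos_C	pos_G	pos_T	neg_A	neg_C	neg_G	neg_T
1	35	25	43	26	26	19	23	21
2	33	32	33	31	24	16	21	28
3	33	21	24	51	22	20	27	20
4	20	41	45	23	21	24	23	21
5	28	33	43	25	24	21	18	26
6	32	26	29	42	32	18	24	15
7	26	32	36	35	20	21	20	28
8	33	28	33	35	22	19	32	16
9	33	34	37	25	19	31	19	20
10	25	28	41	35	20	27	21	21
11	33	26	35	35	12	20	27	30
12	29	34	40	26	17	24	24	24
13	28	37	33	31	15	26	26	22
14	31	37	39	22	13	36	25	15
15	16	44	39	30	15	27	32	15
16	30	41	30	28	16	27	24	22
17	38	33	33	25	16	21	27	25
18	36	37	29	27	17	24	27	21
19	38	34	40	17	22	19	25	23
20	13	63	26	27	21	29	20	19
21	44	8	20	57	31	4	20	34
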