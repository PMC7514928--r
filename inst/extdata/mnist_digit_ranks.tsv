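digit	K1	K2	K3	K4
0	1	4	3	10
1	2	2	1	2
2	3	1	2	1
3	4	6	4	3
4	5	5	7	5
5	6	3	6	4
6	7	8	5	6
7	8	7	8	9
8	9	10	10	8
9	10	9	9	7
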