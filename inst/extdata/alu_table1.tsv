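subfamily	class	count
Ya1	1	3761
Ya1	2	25
Ya1	3	2
Ya1	4	4
Ya1	5	1
Ya1	6	1
Ya4	1	426
Ya4	2	6
Ya4	3	2
Ya4	4	2
Ya4	5	1
Ya4	14	1
Ya5	1	1722
Ya5	2	75
Ya5	3	15
Ya5	4	16
Ya5	5	11
Ya5	6	10
Ya5	7	5
Ya5	8	4
Ya5	9	2
Ya5	10	5
Ya5	11	1
Ya5	12	1
Ya5	13	2
Ya5	14	1
Ya5	18	2
Ya8	1	28
Ya8	2	3
Ya8	9	1
Yb8	1	1489
Yb8	2	71
Yb8	3	11
Yb8	4	15
Yb8	5	8
Yb8	6	9
Yb8	7	4
Yb8	8	4
Yb8	9	1
Yb8	11	1
Yb8	13	1
Yb8	14	1
Yb8	16	1
Yc1	1	3162
Yc1	2	42
Yc1	3	9
Yc1	4	4
Yc1	5	1
Yc1	6	1
Yc1	7	1
Yc1	9	1
Yd2	1	401
Yd2	2	1
Ye2	1	1130
Ye2	2	3
Ye2	3	1
Ye5	1	853
Ye5	2	10
Ye5	3	7
Ye5	4	2
Ye5	5	1
All	1	12970
All	2	237
All	3	47
All	4	43
All	5	23
All	6	21
All	7	10
All	8	8
All	9	5
All	10	5
All	11	2
All	12	1
All	13	3
All	14	3
All	16	1
All	18	2
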