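# Per-sample junction calls of the studied carrier families, long format.
# method: Sanger or PacBio amplicon sequencing of the fusion-repeat junction.
# call shorthand: 1 = JUNC1, 1c = JUNC1C, 2 = JUNC2. Samples without a call
# for a method are omitted.
family	sample	method	call
1	P1	Sanger	1
1	P1	PacBio	1
1	F1	Sanger	1
1	F1	PacBio	1
1	B1	Sanger	1
1	B1	PacBio	1
2	P2	Sanger	1
2	P2	PacBio	1
2	F2	Sanger	1
2	F2	PacBio	1
3	P3	Sanger	1
3	P3	PacBio	1
3	F3	PacBio	1
4	P4	Sanger	1
4	P4	PacBio	1
4	F4	Sanger	1
4	F4	PacBio	1
5	P5	Sanger	2
5	P5	PacBio	2
5	F5	Sanger	2
5	F5	PacBio	2
6	P6	Sanger	1
6	P6	PacBio	1
6	F6	Sanger	1
6	F6	PacBio	1
7	P7	Sanger	1
7	P7	PacBio	1
8	P8	Sanger	1
8	P8	PacBio	1
9	P9	PacBio	1
10	P10	PacBio	2
11	P11	PacBio	1
12	P12	PacBio	1c
13	P13	PacBio	1
14	P14	PacBio	1
15	P15	PacBio	1
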