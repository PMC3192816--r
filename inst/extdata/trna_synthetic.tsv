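id	label	anticodon	amino_acid	gene_copy_number
1	Ala1	UGC	A	11
2	Ala2	CGC	A	5
3	Arg1	UCU	R	11
4	Arg2	UCG	R	6
5	Arg3	CCG	R	1
6	Asn1	GUU	N	10
7	Asp1	GUC	D	16
8	Cys1	GCA	C	4
9	Gln1	UUG	Q	9
10	Gln2	CUG	Q	1
11	Glu1	UUC	E	14
12	Glu2	CUC	E	2
13	Gly1	UCC	G	16
14	Gly2	CCC	G	3
15	Gly3	ACC	G	2
16	His1	GUG	H	7
17	Ile1	UAU	I	13
18	Ile2	AAU	I	2
19	Leu1	UAG	L	1
20	Leu2	CAG	L	10
21	Leu3	AAG	L	2
22	Leu4	UAA	L	7
23	Leu5	CAA	L	1
24	Lys1	UUU	K	7
25	Lys2	CUU	K	14
26	Met1	CAU	M	5
27	Phe1	GAA	F	10
28	Pro1	UGG	P	10
29	Pro2	CGG	P	2
30	Ser1	GCU	S	11
31	Ser2	UGA	S	4
32	Ser3	CGA	S	3
33	Ser4	AGA	S	1
34	Thr1	UGU	T	11
35	Thr2	CGU	T	4
36	Thr3	AGU	T	1
37	Trp1	CCA	W	6
38	Tyr1	GUA	Y	8
39	Val1	UAC	V	14
40	Val2	CAC	V	2
41	Val3	AAC	V	2
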