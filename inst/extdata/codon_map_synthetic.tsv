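codon	species_id
GCA	1
GCC	1
GCG	2
GCU	2
AGA	3
AGG	3
CGA	4
CGC	4
CGG	5
CGU	5
AAC	6
AAU	6
GAC	7
GAU	7
UGC	8
UGU	8
CAA	9
CAG	10
GAA	11
GAG	12
GGA	13
GGC	13
GGG	14
GGU	15
CAC	16
CAU	16
AUA	17
AUC	17
AUU	18
CUA	19
CUC	19
CUG	20
CUU	21
UUA	22
UUG	23
AAA	24
AAG	25
AUG	26
UUC	27
UUU	27
CCA	28
CCC	28
CCG	29
CCU	29
AGC	30
AGU	30
UCA	31
UCC	31
UCG	32
UCU	33
ACA	34
ACC	34
ACG	35
ACU	36
UGG	37
UAC	38
UAU	38
GUA	39
GUC	39
GUG	40
GUU	41
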