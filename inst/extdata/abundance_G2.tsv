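name	copies
Cln3	1
Cdh1	1
Cdc20	3
Clb1	3
Clb6	1
Sic1	1
Cln1	1
Cln2	1
Clb2	3
Clb5	1
const01	20
const02	18
const03	16
const04	14
const05	12
const06	10
const07	8
const08	6
const09	5
const10	4
const11	3
const12	2
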