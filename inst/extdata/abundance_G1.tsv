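name	copies
Cln3	3
Cdh1	3
Cdc20	1
Clb1	1
Clb6	3
Sic1	3
Cln1	3
Cln2	3
Clb2	1
Clb5	3
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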