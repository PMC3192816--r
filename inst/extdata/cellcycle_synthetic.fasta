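>Cln3 synthetic cell-cycle panel gene
GCGAUGAGCAAGCUGUACACACCAAGCGACUCAGGAAGCCACGAAAAGGUAAAGGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAACACGAAGACAACGACAGAGGAAGCGGGUUCUUAGAAGACAGCAUGUCAGACGCAAGAACAAGAUUCGCAUAA
>Cdh1 synthetic cell-cycle panel gene
GAAAUAGGAUUAAGAGAAAAAUGCGGAUGCCGAUUCGAAUCGGAACACAGAACAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGACGAACCAGCGGGAUCACAAAUAUGCGAAAACAGAAGCGAACCAUGGGCGAAGAUGCCAAGAAGCUAA
>Cdc20 synthetic cell-cycle panel gene
GGAUCAAUAGAACAAUUAGACAAAUUAAAGUUCGGGAUGUGCGGAGGAUGGAGCGGGGGAGUAAGAGCACCAGACGUAUUCAUGCGAGCAGGAUGCAUAGCGAUAGUAGAAAUACCAAUAAUAGGAUUCAAAGACCCAACGCUGGAAACGACAAAGAUAAAGACAGAAGAACGACUGGAAAGAUAA
>Clb1 synthetic cell-cycle panel gene
GCAGACGCACCAGCAGUAGACGACUGGCACUGCAUAGGAGCAAGCAAGGGGUUAAAGAGAUUCCAAGAAGGAAGAUCGGACUUCACAGAAAUGAUAAAGAGACACGGAUGCCCAAUAGAACAAUUCUGCGCAUGCCACGCAUAA
>Clb6 synthetic cell-cycle panel gene
GAAUGCACAUUAGCAGGAAAGGUAGACGUAGGAAUGUUAAGAAGCCGAGGAACAAAGGGGGACGGAGAAAGCAGAUUCUACAACCGAGGAGCGUACAGAUUCUACGGAAACAACUAA
>Sic1 synthetic cell-cycle panel gene
GACUACAACGAAACAAACGAAAGAAUGUGCAGAAAGCCAGAAAAGGACUACUGGAGCAAAGAAAGCGUAUACCCAAGACUGGCAGACUAA
>Cln1 synthetic cell-cycle panel gene
AUAACAAGCGUAGACGAACACCCAGCACCAAAGUUAGUAUUCAUAUGCCCAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAUUACUGCAAACAAGCUACCACCAAAGAUUAGUAGUAAACGUAGAACAACCAAGAGACAGCGACGGAUAA
>Cln2 synthetic cell-cycle panel gene
CUGAGCACAACGGACGACUCAGACAAAAGCGGAAACAUAGGAAGAAUAAAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAACAACUGGAACAAGGAAGCAUAGAAACAGGAAGCACGCUGCCAGAAAACGGAAAAAAGGCAGCACGAUAA
>Clb2 synthetic cell-cycle panel gene
AAGGACGAAGUAGAAUACUUCAAAACAAUAAGACCAAUAGGAAUACCAAUGAGAGACCAAUUAAGCCUGCGAGCAGUAAGAAACCGAGUAGGAUUCAAAAGAACGUUCACAGACGAAAGCAGCAGCGCAAAGGACACAAGCUGGAGAUAA
>Clb5 synthetic cell-cycle panel gene
AAGGCGAGAUCGCAAGGAGACGACUUCGCGUGGAUAAACCUGAUGGUACCAUGCGCGAGAAUAGAAGGGAACAUGGGAGUAGACUCAGCAGAAAUAAUAUUCCGACAAAAGAGAGGAAGCGACCCAAAGGAAUAA
>const01 synthetic cell-cycle panel gene
GUACCAUACGGAUGGCGAGCAGAAAUAUACAGCUACGUAUUACAAUGGGACCCAUGGAACGGAACAGCGAGAGAAGGAAUAGUACACCACCCAGAAGCACAAGCGAAGAUAGAAAAACCAAGAAGCGCAAAAAGCAGAGACGCAUUCAUAUAA
>const02 synthetic cell-cycle panel gene
AGAGGAAAGGACUACGAAUCAAUAUGGAUGAUGUCAGUACGAAUAGUAUGCAAGAUGUUCCUGUACUUCGAAGCGUUCAGCGCGAUAAAGGCGAUGGUACACAAGAGAACAACAUUCUGCGAAGACGCAAUAAUGAUAUGGGCAAGAACGUAA
>const03 synthetic cell-cycle panel gene
CAAGACUUCGUAGAAGUAAGCGUAAAGAGAAAAGUACCAUUCACAUUACGAUUCCACAACAACGCAUACUACGUAUUCCCAUCACCAGGAAAGAUGGCAAGAGACAGCCACGCGAAACUGGCAUUAGACGCGUCGAGAAUAAGAUACCCAUAA
>const04 synthetic cell-cycle panel gene
ACGGGAGCAAUAUUACACAAGGGACUGAUGCAAGAAAAAGACAAGGCAAGCUUCAGCUGCUGGACAACGAUAUGCUCGGCAGUAAAGAUAGCAGCAGCACAAUCACAAAUAGGAAUAUUCAGACUGCGAGUAGCAGGAGCAAGAGUACACUAA
>const05 synthetic cell-cycle panel gene
UUACACCGAGAACCAGGAGACGUAUACGACGAAAACCACACAUCAGUAGGGGACUACCACAAGCCAAAGAGACGAUUAAACCUGCUGUACGGAAAGAUAUCAAAGAACCACAAGUGCGCGGACACAGUAACAAGAUUCAACACGCAAUCGUAA
>const06 synthetic cell-cycle panel gene
UUCGAAACAAUAUGCACAGAAAACUGGGGACCAGGAGGAGACACGGGAGACAACCCAUCAACACUGAGAUCGGUAGUAGGAGACAAAAGCGCAUUCAAAACACGAUUCAAAGUACACAUAGAAAAGGCGGAAGAAUUCGGAAGAGCACAAUAA
>const07 synthetic cell-cycle panel gene
UGGGAACCAUGGGGAUUAGCACGAAGCAAGCACGUAGAAUUCCAACGAAGCAAAGGACAAUCGCUGCACAGAACAGUAGUACUGUACGUAUCAGCGAAAGGAUGGUUACAAAUAGAAACAGACUUCGACAACAAGCUGAACGACACAGAAUAA
>const08 synthetic cell-cycle panel gene
UCGGCACCAGAAAGAGUACCAAAAACAUUCGGAGCAGAACUGAGCGAAUGGUGCAGAAAGCAAUCAGGAACGGUAUACGACGUAGCACUGGACAUAGGAGUAACAAAAGACUUACCAAGAAAACAAUACCUGUUCGUAGGAGUAUGGGCAUAA
>const09 synthetic cell-cycle panel gene
AUAAACGUAAUGUUACUGCUGUGCCUGUACAAAAUAGAAUACACAGUAGUACACAGCCACAACCAAGUAAUGUACAUGGGGAUAGACAUGGCGAGCAGCUUCACAAAGAGACGAGUAGGAAUAGUACGAUUAGAAGCAGGAAACUGGCUGUAA
>const10 synthetic cell-cycle panel gene
GAAACAGCAGACUUCUGGUCGCGACUGCUGAUAGCAGGAAACGACCCACCAUUAAGAGGAAAGAGAACACUGGUAGGAGACAAGGCGUGGACAAACCACUUAGCAGGAUUAAUAAGCAAGAAGCGAUUCUACGACUACAUACUGGUAAGCUAA
>const11 synthetic cell-cycle panel gene
AUAGUAGCAGUAAACCCAAUACCACCAUUCUGGAGCAAAAUGGACUACCAACGAAACGCAUACCACCUGAACCACACAGGAUACAUACGAGGGGGAUCGCAACACACACAAUUCGACAGCAAGGCAAUACGAUUCGUAUGCAGAGCACCAUAA
>const12 synthetic cell-cycle panel gene
UCGUUACACAAAGACCUGUUACUGAGCAAAGCAAGCGGAUGCUUAAAAGGAAAGGACAACCUGAUACCAAAAGGAGUAGGACAAAUAAAGAUAGACAUAGUAACACCAAUAUACGUAUUCGAAUGGUUCUACGCAACACCAAUAAAGAGAUAA
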