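>YDR382W synthetic surrogate ORF
GGAGACCCAAGAGUAAUAUUCACAAAGAGCAUAGAAACACUGGCAAUAGACGACGGACAAAACAAACCAGGAGAAUACCACGGAUUACAAUGGAAGAACGCAUUCAUAUUAGAAAGCAAAAAGAGAUACGGAGACAGAGCACUGCCAAGCGAACUGAGAAGAGUAAGAAAAAUAUUCGAACAACACCUGUACAGCGGACAAUUCGGAGAAGAAGAAGAAGAAUUAGGAAACGAAGAAGAAGAAGAAUGGUGGAAGGAAGAAGAAGAAAGCAAGCCAACAUUCUGGGGAGAAAAGAGACAAAAGGGAGAAUUCAAAUGGACAGAAAACAAGUAA
>YLR378C synthetic surrogate ORF
AGCGACGUAGAAUUCUUCCACAGAUGCUACAACGUAGUAACAUGGAGAAUAAUAGAAAGAGAAGUGUACUACGAAACAUUCUGGUUCAUGGCAGCAGACAUGAAGGGGAUGCACCAAUUAUCAGCAGUUGGAGCAUACAAGGAAGCAGUAGACGGAGAAAUUGGGGGACGACUGGGAUUGGGGAGAGUAUCAGACGCACAAUACAAAUACGGUAGAUUCCUGUACCGAGUGUUAUUCGGAAAGUCACGAGAAGCGAAGGGAGCAGCAGCAACGCCAAUAGCGCGACCACUGUGCGUUUGGCAAGACAUGUGGAAGGAAUUCACAAGCUGGUCAGUAUUAAAAGGGCCAGCAUCAGAAAAACUGAGCUUCCUGGUGACAACAGACAACAUAACACUGAUAACAAGAGGUCACACAGCGUUGAGAGAGGCAUACUUCACACUUGACAACUGGAGAUCGCACGUACCACUGAACGGAUUCAGCGAAUCAACAAAAAAAUCAAACACAUCAUACAGCCUUGGACACAGACAAUUCAAGCUGCACAGACCAGACACGGGUCAAUGGUGCGAAAACUACGGGGAAUUCGGAGGAAGCUUCCAAAACGAGGAAGGACUGAGCGCAAAGCCGGAAGGACCAGUAAGCUACGGAGAAGAAAGAAUGAUGUUGUGCUUCUUCGACUGCCAAAAGAAACAAUUACUGUUAGGAAGAGGGAGAUACCAAUGCGGAGACGACCAAAACAUUCUGACAAAGAACGACAACAAGAAGAAAGUUCUGGAAUGGUUCGUAGCAAGAGCAAAAUGGGACGUGGGAGGUGGGAUAGCAUUAAGCGACCCGCUGACAAAGUUAUUAAUAACACCACCAUGGCCAGCGAGCAAGUCAGGAAUAUUCGACAUACACGUAUUGCGAUUAAAGAUAGCGAAGAAAACACUGGUGAAGGCGAUGAACGGAUCAACGCCAAAGCAAAAGUUCCGACGAUUACAACUGAAAGUAGCGUUAAUAGUAGACGUACCAGCAACAUUCAAACCAAGCGGGGAACAAAGAGGAGAAGACCAAGUAUUCGACACAAUAAACAAGCAAUUAUACGGAGGAUGGGGAGAACGACCAUUCUUCGGUGGAAUAGAGUCAGUACACUUCAGCAAGUUGGGAGCAGCAAACCCACUGUUCGGAAAGUUAGAGAUAAAGUUCGGUCCAGCGAGCAAAUGCGACGCGGUAAACAUAAACAUACAAAUACUGAGCAAAGGAUCAAAAAAGCAAGCAGCAGAAGAAUGGGACCUGGUAAAGUUCGCAAAAGAAGUUUUGCAAGACAUAUUCGAAACACCACUGAUUUUAAGAGGAGACAAGACAUUAACAAUACUUACAGGAAGCUACUGCUGCGACACAGGGUCGGAAGGACGAGGAAUUCGAGGAGCGUGGGGGAUAAACUUCAAAGGGUUCGACGCGGCAUAA
>YJL136C synthetic surrogate ORF
UUCUUAGCAAAAUUCAGCUGGAAGGUAUGGGCAUUCAGACAAAAAGUAUUCUGGAAGCCAGACGCAGACCCAUGGUUCCAAUGGGUAAAGCAAGACACAUGGGGAGGAGAACUGGCACGAAAGCUGACAGACGUAAUAAGACCAUUAAAGAGCGGAAGAAUAAAGAAGAAGAAGAAGAAGAUACUGAAGAAGGGAUUCGGAUUCUUAUUCGGAACAUUACCAGCAGGAGAAAAGCACAAAGACCCAAAGCAAAUAUACGAAUAA
>YMR307W synthetic surrogate ORF
GACUUAACAAGAGACAUGUCAAACCAAGGGGUAUUCGUAUUCGAAGCGUCAGUAAGCGAAGUAAACGCAUUACAGCUGGCAGUAAGAACAGUGCAGCUGGUAUCGGGUAGAGAAGGACAGGUUAUACUGCAAUCAUACGUACAGGUAGACACACCAACACUGCAGUACAGACUGGAACUGAGACAGGGACUGUACAGAGGGUUCGGAGAAUGCUUAGCACUGAACAUAUUAGUAAAACUGGACGAACCACAAAGAAGCUUCUGCACAAUAAGAAGCUGGGAACCACGAAAAGUAGUAGGAAGCAUAAUAGGGGAAGGAGUACUGGGAAGAAACCGACUGCAAAUAUUAGUAGUAAGCGACGUAACAAUAAUGGACGUAGAAUUAACAACAGACAGAUUAGAAGGAAUGAGCGUAGAAAUAGGAAUAUUCGGUAGCGCACUGCUGGCAGUAGACUCAGAAUUAUUAGAAGUUGGAGACCCAACAAAAAGCUCAAACAUAAGAACAGAAGGGGUAAUUGUUUGGGUAGUAGGAAUGACAAUAGACAUGGUAAUACCAGUAGGAUCACCGGUAGACAGCGAAACGGUAAGCAGCAACGUAAAGUGCAACGUAAACACGCCAGUACAAUCAAUACACUGCCACGCGAGAACGACAGUAUGCCCAUGCAUAUACGACUACACGUUCGGAUGGGGGCCGCUUGAACUGGACUUCCUGAGCAGACCAUUCUACGAAGACCACAAAGCACUGGUACACUUCGUAACAUUCUUACCGCUUGUAAAAAAGUUCGCAGACGAAAUGUUCAGAGAAGUAACGAUUGUUCACAGAAGCCACAUGUGGCCAGAACUGUUAAUGUACGGAGACGCGUCAAAAACAACACUUAUAUCGGAAGCAAGAAGAUUCUUCUACACAUACAAAUCACGACGACAACAACACAACCCGGUACUGUUAUUAGACCAAGACAAGGCGGACAUGGAAAUAGUAGAACUGAGCUUAGGACCAGAGUACGGAGUAGGGUCACACUUAAGCGGAAUGGUACUUCUGUUCUACAUAGGGGCAUGCGCGUGGACAUUCAAAGACAUUAUAGCGGCACACAUUCCACUGGACUACAGACCGCAAGCAAGAACGUUAAGAGCAACGCUGUUCGACACACGAGUAAUAACAGUAGAAUCGGACGAAGAAACGGGGGUAAGAUGGGACCCAGACGUAUACGGGUGCUGCAUUUGGGACGGAGUACUUGUAAACUACGCGGUGGUAAUGAGAAACAACAGCAUAAUUCCAACAAGCUACUACUCGGGUGAAACAGCAGGAAACUUCGGUUGCGAAUCAACGCCAAACUUACCGUCGUGCAUGUACCGACUGGUAAUAACAAUAAACAAAUACGGAGGAAAAGUACACGACGCACACUUCGAAAACAACUUCGGAGGAUCGCUGACAGACAAAUUCGCACUGGGAGAAGAAGUACUGCUUGGGGCACCAGUAAUAGGAGAAAGCUGCGGAGGAUCGGACCAAGUGCUGUUAAUAACGAUUCUUCACGCAUACAGCCACGGGAACAGAAGCAUAAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGAAGGACCAAGUAAGAUGGCCACUGUGGAUAGCAAUGGGACUGCCAUGCAGCAGAAGAAACGAAUUAAGAGGAGGACAAUAA
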