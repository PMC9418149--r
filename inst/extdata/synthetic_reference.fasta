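>synthetic-D-loop-1232 synthetic stand-in reference, 1232 bp
TTCTAAACTAACGGTGTCGCGCGAGCCATGCGACCGCTTGCCAGGTGCTTCTGTGATAAG
TAAACTAGCTCAAATGGTGGTGTGATATGAAGTCAAGCTTGAGTCTTAGAGCAAGGAAGT
GTCTTAACAGTGCTCTGAGACGCGTGTGTGATTACATCATACTAGCGCGGGTTGTAAATG
TTGACCGGCCCTCAGAGGAGTAGGGCTCCCAGGACAGCTCAGCGGCACTGGGGACGATCC
TGGAACTCACAGCTCGTCGAATAACAGTAGCAATACTTTCATCGAGTTGTGCAGTCAGAG
GGATGTTAGGAATGGGTTGTGATTATCTCGATTTCGGCCGCAGAGTGCCAGGGCTAATAC
TACAACCGGATTAGGAAAGTTAGGTCAATGCCATTGTTTCCTTGGTTGTGCGACCACCTT
GGATACACCCTCAGACCCGTCTCTTGTTGCCAAATTCGACCTATACGAGCGTCTGGGCTG
TAGCGCCTTAGACGAAGATCACAAGAGAGACAGTACAGTCGGGCAGGTATAAAAAGTGAG
CCGCTCCTAAGGGGCCTAGGCTAATATTCTGTTTAGGGTACAATTGTGACTGATTGATAC
AGGTCATCGATCCATCGGCTGCTTAATGGCTAAAGAGCCTCAGCCGAGTGCTCTTCAAAA
TAATGGTCGCAATAGAAGGAATAGTGAAAGTTATCCCTGGCCTTTTGGACGCGAAAAACA
CGTGGCGACGGGCCGCCCGATCGCAGCCCGGGGGGGGACGAAAACCTGGAGCGGTCTGTG
GCGAGCGTCTCTTCTTCTTGGACTGGAACTACAAGGGCTAACGATCCCCACCACAGGGAC
AGGTCGCCAAGTTTAGGCGTCCACTTCCATCGATCTACTCGATGCTCTATTAGTACGTTC
GTTTGGCCAGGAGCAACGGGAAATAGCCTCGCACGGCTACCCGAATACATGCTCCCTCTT
AATCTACGACAGGGAGTCGCCAGACTAAAGTCACATTGTCCTAGAACTAGGAACATACTA
CATACGCCTTTGTGTGTTCCGCGTAGAGACCGCACACGTCGTTTGTGGAGGGACGCAGCT
ACAGATGGCCCGGTAATTCGAGCCGCTCTGAGAGAAACCACAAGTTTCTGCCAACGTATT
CCAGCCGCCGAGTGTTGTCCATGACAGCCATTTGGCCGATGGCCGGTATCTGTTTAGATA
GTGGCTAAGCTGGTCCCCTGATTGCAAAGCTG
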