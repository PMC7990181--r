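>chr1
CGAGGAAACGGGGCCGATTCATGACTGCACCGACCTTAGGGCCCTTACCTTTTTTTAGTTAGGCAGGTGC
TTTACTCTACGAGCTATACGATGTGGTGTACCTATAATACACACGTCTATTCCGACTAGTAAATGGTAGG
ACGCGCGTTGGAACGGACACTTCGCCGGACTCTTCGAATCGGGGAGGGGGAGATGGCCGATATTTATGAC
CAAGATTCGAGAAAGTTGAGTGGTTCGACCCTTTCTTAGGTACTCCCCCGAGAAAAATCAGCAAAATGGC
ACAGCCAGGGTGACAAACCTAGGCCTCGCGGAGGACGAGAGGTCTCGTCCATCTATGTTGCACTGATGAG
ACGGGATCGACATTAAGTAAGCCCCGCATAGTCTAGCTACTTCCGATTGTGGTGCAAGGACTCCAGGCCT
ATCGTGAACCTATTCACGCATGCCTTTGAACGTGGCCTTTGCATCTAATTTGTTGACGCGCATCGTCCGG
GAACACGAGATGTTAGATCTGTTATCAGTTTAAATTCACTGACTGAGCGGTTGCGGTCACTGGCAGCACA
TCCTCCCCCTTATTAAATGCGGACCTTCCAATCTTCATCATATCTCTGCGACATACTGCGTTTTCTATTT
CGCGATCTCTTGGGAGGATCTGCCAATGTTGCGATTAAACGTAATTTCATATACTGCGTAACACATTTTG
AAGATAATGATTCAAATTCTCGGCACAAGGCCCTACGAAGTAAACGTGATCAGAGATTGCGGCGGGCGTT
CAAGGGTCCCTCTGGGAAGACACTATAAGAGCGTTAGAAAGGAGCTCAATCAACTGCTTGCGGAGGTTGC
GGGACGCCTGAATAACTCACCGTGTCTTCCTAAGATCATCAAAAATCCTAAGGTACTCCCCTCCAACATT
AAACGGACAACGCTATTTTGTCATGGCTCTTCCTGGGAGATGCTTTTGTGTATTACTCACATACGATAGC
TGACGTGGTCACGAACGGCTTAGTTTTCAGGAGATCAAAGCGTGTTGTAATGGAACACGAGTTGGCGGGT
CAAGGGCAACCGCTCGAGGGTAGTACTATATACGAAGGCAGCTCAGCGGTTAACGCATCTAATGAAACGT
AACCGGCCCATAGGTTTGTCTCACCGGTAAAGACACTCTCACCTGTGTGGCCAAAGATAGGACTCCTCTG
AACGAGGAGGCCTCGCGGGGTCGCTCACCGACGGTATAATACAGGTTCGTCCATCACCCATTCAATCGAT
TCACTGGTCCTAACCTCGGGACCATCCAGTTTCTCTTGAGCGGCTTCAGCTCAAGGAGACCAGTACTTGG
TTCGTTCAGGCTTTAACGTGAAATTCCGGTGGCCCAACCAAATTTAGCGTAAAGACAGCAACAGAGTGCA
GACAGAGGACACGAGTTGCAGGTACTTGCAAACCCCGATGTATCCCCTCAGTTAAACCCACGCAGCAAGA
TCTAATTTACTATGGCAATGGGAAATGAAGATCTGGGGGCTACGAGAAGATTTCACAAATGGTTAACGGG
CCGACTCTTTTTTTAAGCATTTATAAGTGTGGTTGTATTAGAGACCGAACCTGATCTGGTGTGCAGCGAT
CCAAGACACCTACCACTTACCAGTCGTCCCAGCGTTAATATAAGCAGCTCTCCAACGGCATAATCGGATA
GTATGACCTTACAGTGAGACCGGGTTCAGTAGCTTCAGCTAGCCTCCGCACTCGTATTAGGGCGCCGATA
TCCCGGTATAGAACTATTGGGCAGGAGGAGTCGATGGTTTCTAGCGATAGTAACCTAGTAGCCTGGAACA
CTAGATTTGGATGTTACTTTCCTTTCCTTTACTGCAAAGCTGATCCCATCACATTCGTTACTTGCTAATA
CCGGCGCTTTATTACATTGACCCTCAGAACAACCCCAGTAACGTTAGAGACACTCGACCCGTGGTCCATG
TGTATATCATGACTCTGAAATGGCCGGAGACGTTAGGACGATGAAGTGTCGAGTGTGGGTGCCTTTATCC
GCTGGCGACAAGAATACTAAGCTACAAAGACCGCGAGTTCATATACGTTTGCGGCCTCAAGTGTTTGCTG
CGAACTGACATCCAGGAAGATCCGCAGCGACAGGAAAGTGTCCAACGCTTTATCTACTCAGAAGTAATAT
GCGGATGAACTTTTACGGGGGAAAACACTCACATGTACCGATGTCGGTGGCACCCGGATTCTCTGGGTTA
GACCATCAATACCCATGCCGAGTGCGGATATAGCGCAAAGGTTTAGAGATGCGGGGGCATACGCAGCGCA
GTCAGGTCCTTCCATGGCCGACCTCGGCAAGAAATCCGTAAACCCATGAAGGGACAAGCAACGCTGCACT
GGGCGGAACTCCGCTCCCGTGGCTCCCATGTCGCGCAAATTTGGACTTACTCGACCCCGAGTGTATAATA
ATACTAGAAACGTTCAGTCAATTTGATTCTATATTAACGAATGACGTTTAGAGCGGGAGGGCGCCCAAAA
ACATGGACCATATCTGTAAACTGGTTAGAGAGAGGAGGAAGCTCGGCTGAAACTTGGTGAGACTAAAAAG
GTCGCTTCCACGGTTTGGGTTTTACATTATGCATGATACGGACAGTCCATAACCGGTCGTTTGGCTCATG
GCAGTCCCGACCGTAGGGTATGAAACCGGGTTGCTAGGCGGAGTCGAAGTTACGACCGGCATTCGTTGGA
ATGCTCGCAAAGTGCTGCGTGCATTAACTAACCGCTTGCCACCATGGCTTCACAGACCGGCCCGATGTGT
GGATTGCGGAGATATCAGTACCACATTAGACGTAGTCGACCAGCGCACCCATACTTTTCTGACTTTAGCG
TGGAATACTTCAGCGGGGCTCCGATTCTCCATCTCGGTACGGCCTCGGGTGGGGCCGAAACTATCGGACC
TCAATCTCGTAAGTCTGGAGAGCACTGGTTTTAACGCGACACAGCATATTTCTGGCATAC
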