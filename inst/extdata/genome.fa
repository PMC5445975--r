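>I synthetic demo genome, seed 4242 (not a real assembly)
AGCTTAACTACTCAAACTGCCTCTTGAGTGGCATCCAGGGTCCGGTGTGCAACTATCGATCACCACTACT
ATCCCAATCAGCGCAGGACCCCAAGCTGTGAGGGCTTCAAAAGCGTAGGACGTTTGAACCGCTGTAAGAT
ATCCACTAGATATGGCTGGAGATCCAAAACCTAACCTTCGGGGGGTACGGCTTAAAGAAGGCGAGGCGAA
TGATGTCTGCTGCAGGAGAGTACAAGGGTGCCATACAGAGTTGACCTAGACGCCGTCACAATCATAGATG
TAGCAGCCATCACATACTGTCCTAAGGGGATCCTGGGGCGCGGACGAGGCGGAGTAGCCCTCCTTGAAAG
ATTAAACCGACACCAGAACTGTATATGGCCAAGCACGGCAGTTCCTGGACCGAGAGGCCCCGTAAAGGGC
GAGACTGGTATCAGTCCGCATAAATAACCCGATTCTCAGGAAAAGTACGGGCGACTTGCAGCGATCTTCC
AGGAACACGTAAACGGTGTAGGAATCTTACATGCGGCAAGCGTACCATAGGGCTCAAGAAGATGACGTTA
CCTCGTTACTGTGGCATCAAGCAGTGAGATCGTCCCTTAGCAAGAATTGTTGTGGTTTGCAAGGTACGTT
TCCCTGATTCTCGGATAGCTAGGAAAACGGGCCTCGCTATGGTAAGTGTGACTTGCGTTACGGACACGGA
ATAATTTATCAGGTAAATCGGCCTCCCCGTCACGAAAAGCCGGGACGACCTAGCGTCAAGCTCACTCACA
TTATCCCGTTTGCTCCGGAGGTTCATGGTGGTATGGGGAGCCGTCACTATCCACCGCTTCGAACTTACCT
CTTGATATGTGCGACGGACCCATACTGCTTAGACCGGAAGGTTGTACGTAATACAACCGGGATAGCCGAC
TCGAAGCGCACCATAGTTTATTAACACGTCCGGCGGTGCCTAGAACCTACGACTTCAGCCCCCTGACAAA
CAAATTGGGATTCAAAACCTCGTATGGAGAAGCCTGATTAGAGTTTGGCTTCGGGTAATGGTTACGTACT
GCTGAGCTATCAAGAGTTTATCGCATTCATAGACTCCAGCATACAGAGACCCTTACGGACATAATGGAGA
CGTGCTCCACCATGCGGGTTCGTGCACTGACTCCTAGATGGGGCACATGCGAACCCACTGTCCCGAGAAT
CATCTTCCCAAGTCCAGCTCTAGTGCGAGCAAGCACAGCAGTCCACGAAGCGCACTATAACGAGGCTCCA
GAATCCCCTTATCGTCCGACTCCGCTCTATCTATTATATGGCCTTGTCACGACCAGCAGTTTTCTAGGCT
CGTAACTTCCCTAAGTCGTAGCAATTAGCCAATCGATGATAGCGATCTTTATAGCTGGTGGTGATTTGAC
CAGATGGGGGCGGCTCTGAGGGCTGAAAGTTGGCGGCCTCTCCAGACGCAAACACTGGACAGCCAATATC
TGAAATTAAGCTGTGGTTTCCGTCAGCCTCAACGAATAGAAATACCGCAATTTAATGTGCACTATCGCTG
GTCAATGTCGGTGTTTGAGAGTGCTGAGGCCTAGCGGTCCTCATTCATAAATACTTCCCGGCAGGGGTGA
GCACGTTGCACCGGATCTCAGGGCTTTATGATGGCAGCGATATAAAGAGACCGAGCGTCGAAGCAAACCA
AGAATACCGAACCGTACTGCGCTCCGAGACAGCCATGTAACATCTCTTCATAAAATGGACTATGTTACAG
TTCAATGCAGCGGTAAAATCCTCACGAGTCTGCGAACGGATTGTCGATGCCTGGGGCGTTGTTGCGCCCA
GCTATCCTTGCGACCATTCACGTATTCCTAGGTCTAATAATGTAGTTTCTCTATAATAGGTTTATAAGGC
TCTACGTGCTTAGCCAACGAACCCGGGATCATCAACCCCTTTCAAACAGTAGCGACGGCTGTACACTTAG
GTGTGGGCTTCATAACACCTGGCCTCTGCGGTTTGTCTCCATTTGTTTTGTAAGCGCCTAACTCCGAACT
GCCGTCCGCGCAATATGCCTGTCAGACTTGGGTCCTGAGAGTGATACCATTCTGGTACAGCCATTGGGTG
CCCCGATAGGAGTGCTAATCTCAATTTCGAGACCGGAACCTACACTCTTGCAGGACTGCCAGGACCGCTC
CACTATATACAGCTCCGGGGTATAAAAATGTGGAACGGATGGGCCGGGCTGGCTGGATCTTTGCCACGAG
TCCGTGGGTATAACTCGGGGCGTCAGTCAGCTTCAGGTGCCCATCACTTGGAATGACTTGTAAACAAACC
AACCAATACCCTGGCACAGGGCCGGATGCGTCTGCGCGGTACAGGAGATACGATTGTGATAGGGGGGTCC
CCAGAATGGCCGGCTGGCCGCTCAACCAGAGGCGTACTATTCAACCCTGTATAGACCGGATACCCAACGA
ACTCATTCCTCATCTCTTTGGCCATACCCGACCCAGCCGGGGTGGTGACCTCGTGCGGGGTCCGTAGAAG
GAGCTTCTTTTTGATTTAGAAAACTTAATTAAGGACCAGACACAAGAGAGGCGGTAGAAAACTGGTCCCG
CATGCGTCTACACCTCTAGGGTCAGTCGGTGAAACCACCCGGCCTTTTTAACGGCTGACTCCACGCATGA
AACCTACGCGTTCGCGGGAGTTAGGATAGGAACAGTAATGAACGGTACTATGATTGCCGACCAGCAGCTT
GACCTAGGGTTGAACTGTGGCCTCTATTCGGTTCGAGTAGACGAACCGGAGATTGAGTGAGACGATCAAG
TACGCCGTTGTTTAAGACCGGAATAATGGGACACCCGCTCCAGTTTGTCGCTTAAGCGTATCTGTGGTGG
TACCTCGCATACGCCCCGACCAAGTATCATCCATGCTAAGCTTTACCCTAAGTGGGGTTGTGTGTCCTAG
CGCATTGTGCCAAGCAGGGACAGGGAGGTCTTCTAGTCTGAAGTTCAGCACACAATGACA
>II synthetic demo genome, seed 4242 (not a real assembly)
GTTCATCGCTAACCAGCATTGCCCAATCTACCAGTCCTGATAAGACTATATTAAGAGAGGGTCTTGAATG
CGACTAGATGAGGTTGGCGAGACTGCTTGCAACGCTCCTGTTTCGCTAAGCTCTAGGTTATATGTCGCGA
ACATAACGCTTCGGTCGCAAAGCCGATTCCGAGTTCGTCGATGATTTGCGGGACCTGGCGCCTTAACAAT
CTGTATGAAACTAATGAAGGTGTTGAGGTCTGGCAAAGGTAGTTGCGACGCGGAGATCCCACTGAAGGAG
GACTACAGTCATATTCAGGACTAGACGGGCGCTCCGCGTACGGTAGGTAGACGCGGAATAGTTAGGCTGT
TTCCTAGGCGAATGGAACGATACTAGGAGCTACAGGACCCCACGGACACCGTAGGTGTCCGATAACTTTG
GCGGTCTGAGAAACATTCAGGACCCGCCACAGGAACCTAATAGTATGCTGCGTGAGACAGAAGTTGGTTG
CATGAAGATGGGACCCGGAAATAGGAGGAGTGGGACATGTTAAGGGAACGGTCCATGTCAGACAACCCCG
ACACGATTACATATGTTATCACGGGATCGAAAAGACTCGTTCGGGACTCCTTAGTGATAGAAGCCGGCAA
GCCTTCACCTCCTCCTAGGTAAAGATGGTACTACGAAAATTGTGCCGCACGGGAGTTCCGAACACCTCCG
ACGCAGGGGTATGGACCCAATAACAGTCCTGTTGAGTTAACTCAGTGATTTGATGCCGCATTTCGTGGCA
GATGGGCGTCGGCTTCGCTGGATTAGGTGAGATACCCGCGCAGCGCCGGTCCATCCGACAGCAATACGGG
CGTCAGTCGGGTGAGTAGGGGGAGGTCCGTGAGCAAAGTAGGACGGGAGTTTCCTGAGATACCGACATTG
CGGTAGCTAACCGGACCCCATATCTGATAAGGGCGCTGAAAGTGTATCTGCATACGTCATCGCAGATAGC
CCTCTTCGCATGGTTTTTGTTCCTCGCAGTCACTTTGTCCTGGTATAAGCCTTTGAATATGCCTGGAAAA
ATGGGAGGAAGCGAGCGCAAGGTCTGAGATCCCTGGGACCTTCATGGCTGCCTAATCTATCCCGTCCGCT
ATTGAGAAAAGAAAATCTGTGGGTGAAAGAAACGGCTAGAACCCTGTAGTATCCCCCGTGCGGGAAATTC
TAGCGGTCGTCGAGTGGACTGATAAATAAACTTACATGGCTAAAATCCGGAAGCGCTGCCAACCTACATG
GTAGTAGGAGCGTTGAGGTGATCAAGCAGACTCTTGCCTTGATCCCAAGGTGTACGGCTTCGGTCCGACA
TCTCCGTATGTTGTAGTATCATTGAAAATTTGGTACGCGCCAAGTAGCTATGTGAAACCTGATTTATGCC
ATCGCCGTCTTTACCACCCGGTTAAACTCAACTACCTCTTCATTAACGACTATTCCATGGATTGAGCCCT
TGAATGCTCGTTTCCGACACCGGGCCAAGACTACGGGGACAAGAGAGCCGAGTCGATCCGGCACCCGAGT
GTTAGGGCGCACTCTACTCGAAACTAACTTCTGTACCCAGCTTTCTTAACCCCGGTTGCTCCTTCCCGTT
CCTCCAGTCGGGAATTTCCACATTTGGAAGTTGTGGGCTGGGGTGGGCTCCCTCGTACTGGATATCTGCT
TACACCGTGAACCACAACCTGTTCGCTTGCAATTTCTTTTCGACGTTACACCCGACCAGAACCAACGGCT
GTGGGACTTACAGGCCTTCCGAGCAAGACGGGCCCGCCTAGCCCCGATTCGTTCCCGGCAATGCTTTTCA
TGGGAAAGCCAGTGCGCCATCAGACGAAACACGCCCGTCTCTAGACTACAGTCGTGCCTAAGTGCTGATA
AGACCTAGCGTACCCCGCAATGTAAACCACCTCTTCAACTAGTAAACATAACAGAGCATTCTTGGAATAC
CATCACAGCCTCAGCAGATGTTCTGAGCAAGAGTTAGCCCATATCAGGCTCTTCGGAGGAGACGTGTTCT
TGTGGGTCATAGAGATGGCTTGTGACACTTTTCCTTCTCTCTCGGACAGTGTTGAGGGGCTAACATAGGT
TATATCTAGTACGAGGACCTGTGCAAGTGACAACGCAACGGGTCTCGGAAGATTCGCCAAAGGAATTTGC
TCTATCCGCGATGTCATGCCCTGAGGACGGTTTAGTTTGCTTCACTACCGATCGTGCAAGGACCTGCTCC
CCATGCTCATGACTCCTGGCGATACCAGGGGTCGTACGCGGGATCATATCGAGTCCTATCTAAACGGGCT
GTCGCCTGTGTTTGCGTTTGCGAACTAGCCGTCGTCTGGGCGATTATGATTCCAGTGGTGTCGCCAGGGA
CAGGAGCGAGGAGTTCCTGAGCGTGATTTCTTCTACCCAGACGCTCGCGGCATCAGCTCGTTTGTCCTTC
CCGTCGGCCCCACGGTCCAAGGTTTAATAAGACAAATGAGGACTCCTTACGTGCCAATTGCATACCATTC
ATCCGGTACCGTCGGTATAAGAGAGACCTAACCCCTATAGAGGGCGCTTGCTGGGCCTCATACCCCAGTT
GCTAACGTCGAACGGCGGAAAGTGCCCCGGTTATTAACATTGAGTGTAGGGAGCTATAGCGGTGTGTTAT
ATGCTAGGTGAATTGCTTCACAGTAACACGCACAAATGGCGACTTGTGAATGAGAGTGTCCGACTGTTTC
GTACGGGTGGCTTCTTTGGCGCTCAGAGCCTAGTTCGCACACTTGTAGGAACAACGCCCGCTGAGAGATT
CCTTTCGGCATTGTGGATCACTTAATAACCGGATACCAGACGGGTCTTGACGGGTCGATCGGCATTTTAT
CGACCCAGTCGAGGACCTAAGACTCAGACGCGTGAACAATGTATCTTCATAAAGAATGAGAGATGTGGCG
ATCTATTGTATGTATGCCTCGGTTCTATTTAGATCAGATCACGTGTGCCATTCTAGGTCG
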