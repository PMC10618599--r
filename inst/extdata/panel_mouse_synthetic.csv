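name,reference_sequence,start_anchor,end_anchor,repeat_size,bp_modifier,reference_repeat_count,snp_modifier,notes
18-3,TCCCAGAATGAAATTGAGGTGAACTTTTCAGAACGATCTGCCTGTGCCGAAACTTTCGTTTAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATCTCGGGAACTACCAACGTTGCACATTTATTGGGGTTAGGTCATTCAAATTAACTCAGCC,AACTTTCGTT,TCTCGGGAAC,4,0,17,,
4-2,GAATTTTCGATCTCGGCAGGGTTTTAGGGCCTCTCGCCCGTCTATGCGAGAATTCGCTTGGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGTCTTCGCGATGAAGCCCGCAGTTCCAACTCCTCAGATTTGCATACACAAGAAGGTTTGG,AATTCGCTTG,GTCTTCGCGA,4,0,19,,
5-5,GTGTACCACAACGCGTTATAGTTGTCGCTTGTAATCACCGTAGCCAGAATGTACATCCTCTCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATGACGGCCTGAACGCCACGTTTGTGGTAATGACTCATGCCCCAATACGACCCGTAGATCG,GTACATCCTC,TGACGGCCTG,4,0,14,,
6-7,GCCAGGGCTTGATTCAGTGCTCTGTCTTAGTATCCGCAGTAGATCCCCTGCTAACCCTCAAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATGTCATGATGTATGCGGGAAGTCGGGTCGGACTCTTGATGTTAGCGAGCCCAGCTAACGGT,CTAACCCTCA,GTCATGATGT,4,0,12,,
9-2,CTTAAGGTCAGTGGAAATGCCGTTAAAAGATTAACCTTGTTGCACCCAACGAAATTTACCGGATGGATGGATGGATGGATGGATGGATGGATGGATGGATGGATGGATGGATGGATGGATGGATAATCGGGAGGCTTGTCTCACATTACTTTTGTTCATATCGACCATACAAAATTAAACCCGT,GAAATTTACC,AATCGGGAGG,4,0,16,,
12-1,CTACTCAACCCCCGCATGACGCTATCAGTTCTAGCTCCTAATGTTTGGATGCACCGGTGGTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCGTAAACCATGAAGTCACGTATGGCTCAATGGTAGTGAGGCTGAGGGACTAAGTTCGTAAT,GCACCGGTGG,GTAAACCATG,4,0,15,,
15-3,AGGCCGGTTACCACGTCTGCAGTTGTCATACTCCCAGACTGCCCCTATGATACGTTTAAGAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAGACGGGAGGATATTTTTGATACGGCATCTTGAGTTAGTCTGTCCAAGACTTTAACCGTTT,TACGTTTAAG,GACGGGAGGA,4,0,20,,
X-1,CTAGATGTCGCCATATTACCAGCGATGTCCCTGCACGTGCATATGGCCCTAATAATTAAGGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAATGTGATTGGTACATTTCACAATATTTATAGCGCTTGCGAGCGAGAAAAGGATATTATAC,AATAATTAAG,ATGTGATTGG,4,0,25,,
1-1,TTTCTCGCGCGACCAAGAAACAGCCAATCCTTTTGATCATTGTAGACATGGTGATACCGCTAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGAGTTTTACCAGTAACTTGTCATGCGCCTCAATTATACGTAGCTATAATGATTCAATGGATG,GTGATACCGC,GTTTTACCAG,4,0,13,,
2-1,TAACACATCTCGGGCGACTCCCGCCCGGGGTATCCCGGTCCGCCGTGGTCTAGAAGTACTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTGTGTTTGCAAGCCAATCCATAAGCCACACCTACGCCGGGGGAGAACGGTCGTGCCGTCAT,TAGAAGTACT,GTGTTTGCAA,4,0,14,,
3-2,ACTCAACCAAGTCCTGTGTCACGTCACTGGTCTACCTACAGACGAGCGCTAGCCGCTGTCTCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTACGTCCGACGGGGGAATGGGTTGCAACATAGGACGCATTCCAAAACCCGTCCATAGAGTCC,AGCCGCTGTC,CGTCCGACGG,4,0,12,,
8-1,TGTTCCGGAGCCTGGTACGAGCCACGATTTAAAACTCCCTGTGACCCAATGTGTATGGAGGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATACTTTCCGCACATACAGGCTTTGAGGACGGCGAGGCCTTTATCGAACGCAGGATAGCGATG,GTGTATGGAG,CTTTCCGCAC,4,0,16,,
11-2,CAGATAGAGCGACATTTTATACCGCTCATGATTATGAAAGATCCTGGGGACTAACGAACGTCCATCCATCCATCCATCCATCCATCCATCCATCCATCCATCCATCCATCCATCCATCCAAGTAGGTTCTTGTAGATGCTCGTGTTTGAACGGTCGTGGATATCCCGATTTGTTTGCGAA,CTAACGAACG,AGTAGGTTCT,4,0,15,,
17-2,GCTTGTCCGGCGAAGGAAGTGAACGAGTGAGAGTCATGTCTGAAAAGCGGCCCAGCTAGGAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAACCTATGCAGAATCAGACAGATTGGTAACGACCTGCGAACTTGGGGTACCCAGCACCTT,CCCAGCTAGG,AACCTATGCA,4,0,14,,
19-2,CTCTCGCGGAGTGGGCTTCTCGATCTTAGCCACCTCTGAGAGGGAATTCATCTGTACGGATTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCATCCGGTGTTACGTCCTCTTCGCCCGATAATGAGTAGCTTATAATACTGATTTAACAAGG,TCTGTACGGA,ATCCGGTGTT,4,0,18,,
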