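name,reference_sequence,start_anchor,end_anchor,repeat_size,bp_modifier,reference_repeat_count,snp_modifier,notes
CSF1PO,GGGGTGTGCCTTTTTAAGCGCCTGTATCGCCGTACTATCTGCCCTACTGAAAGATACTTTAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATATATCTGCGCTTCCTTAAAGAGGCGGGCCGAATCCCATACGCGACGTACCACTCGTTAGG,AAGATACTTT,ATATCTGCGC,4,0,12,,
D13S317,TAGAGTACAGTCAAACATAGCTGAGAGACACGCAGCCCGTGCACGCTCCGCTGTACGGGGTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCAATCAATCATCTGCAGGTCCAGCCTCGCCAGCCGTTGGTGCACTCTGGCGGAATTCCAGG,CTGTACGGGG,TGCAGGTCCA,4,11,11,TATCAATCATC:+1,A>T termination variant adds one TATC repeat
D16S539,ACAAATCGGCGTGATTCTGGAAGTAGATGATCGTGGCCCAATCTCTGATCCCCGTATCTTGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAAGGATCGGCAGTATCACCGAACTCGGGTCCCAAACTATCTGTCTCATGTCATCTTTGGAG,CCCGTATCTT,AGGATCGGCA,4,0,11,,
D18S51,GTCAAATTGCCCAGCGGGATGAGTATGTGCTTTAGCGATATAGGAGGATGGAGGTTAAGTAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAGAAAACGTTCCATGAACGTAGACACGCGAAGACAACAGATCACGTCCAAAGAACCCACGCACC,GAGGTTAAGT,AACGTTCCAT,4,0,15,,
D19S433,CACTTACAACTGTCTGATGGCTAAGATCTCCTGCTGTACCGTCGTTTGATACGCCTAAGTAAGGAAGGAAGGAAGGAAGGAAGGAAGGAAGGAAGGAAGGAAGGAAGGAAGGAAGCCTCCACTTACGTTCCTTATAGTCGGAGGCTCCATACACTGCACGGATTCTAACAAGGC,ACGCCTAAGT,GCCTCCACTT,4,0,13.2,,reference carries a 2 bp partial repeat (microvariant 13.2)
D2S1338,TATGTTACGAAGTCGGAGGATGCTACCGGCTTTCCGGGTAGCTTCGGTGCAATGGTTGGGTGCCTGCCTGCCTGCCTGCCTGCCTGCCTGCCTGCCTGCCTGCCTGCCTGCCTGCCTGCCTGCCTGCCTGCCTGCCCGGGTCTTAGAATACTGGCCGACTAAGTGGAAGTACCCGGAACGCAACGACCCGTCGGCG,AATGGTTGGG,CGGGTCTTAG,4,0,19,,
D21S11,GGAAGGGTTGGTGCGAGGATTACCGAGACAAACGGATTGTCGAATTTGGAGCGAATAAGATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCGTCTATCTATCTCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCCAGCGTGTAGACCCACATGTTATTATTAGTGTAGATCGATAAGTCGCTCGGGGTAGGA,GCGAATAAGA,TCCAGCGTGT,4,13,29,,13 fixed non-repeat bases inside the repeat region (bp_modifier 13)
D3S1358,CGTCTTTAGCGTCGGGGCAATGCGTTTGGGAGGACGGGTATGAGAAACGTGTTTGCATCCTCTGTCTGTCTGTCTGTCTGTCTGTCTGTCTGTCTGTCTGTCTGTCTGTCTGTCTGTCTGTCTGTAATATAAGTCAACGGCGGTTGAATGAACCTCGTAATTGATCTCTCTTAACGCTTCTGAT,GTTTGCATCC,TAATATAAGT,4,0,16,,
D5S818,TCGCCGTCACCGTCATAATATAGCCAGGTGAGGGCCGCCACATAATATGCTTTCGCCTACAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATCGTAACTGGATCGGACTTAGGGGGGGGGGCAGCCACCCGGTGTGGCACCTAGAAACTTTA,TTTCGCCTAC,CGTAACTGGA,4,0,11,,
D7S820,CCTTTTACCATAGGCAGAACGGAGCCCGTAGCATCAGCCGATCTGTCCAGATTGGGCCCAGATAGATAGATAGATAGATAGATAGATAGATAGATAGATACGTTCTCCTCAGTATAATCCTCGGCTTGCCAGATAAGGGAGTGAGTCCTACTTTAGGTGT,ATTGGGCCCA,CGTTCTCCTC,4,0,10,,
D8S1179,GTACAAAGTAACCGATAATACAGGGGATACAGGGGGCTACCCCGGAGAAAGACAGAATATTCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTAGATTCAGAGAGGGCAAGGGCCTAGCATCCAGTCTGGTTTGATTACCGTGGCGCGGAAATA,GACAGAATAT,GATTCAGAGA,4,0,13,,
FGA,GAACACAGGTTTGGGACGGATAATGACGGGCGCCCTCGCTATACCGTGAAGGCGATGCGTTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTTTCTAAGGTACGGCATGAAATCATCGAATATAAGATTGACCTTGGCCAACACCTTCTGGACAA,GGCGATGCGT,TAAGGTACGG,4,0,21,,
PentaD,CCATCGCTCACCCGCACGCCAGCAACGCCCACATTCTCGTCGACTGGGCTAGTCAACAGCAAAGAAAAGAAAAGAAAAGAAAAGAAAAGAAAAGAAAAGAAAAGAAAAGAAATTACATCAAGTACTTAGTACTAACGTTCGAAGGGTGACAGAGCATCAGCAAAGTGGTT,AGTCAACAGC,AATTACATCA,5,0,10,,
PentaE,AGTGACGGGTCAAAGTGACCGGCGAATACCGGTTCGACGGTACACGCTACATTCGACCGCAAAGAAAAGAAAAGAAAAGAAAAGAAAAGAAAAGAAAGCATATTGTTTGCGCGCGCTCAGCCGACTTATAGTCACCCGTCTCCAGGTAAAACAAA,ATTCGACCGC,AAGCATATTG,5,0,7,,
TH01,TGGTAAAGGACAACGAACAGGCTACAAGCGACGCCTGCGAGTCTGCCCCTACTGCCGATGAATGAATGAATGAATGAATGAATGAATGTGCTCCATAGGTGCACCCCATAGGTGCTGCCATACATAAAAATCTGTCACAATAGGTTCA,ACTGCCGATG,TGCTCCATAG,4,0,7,,
TPOX,GAACAAGTTCGCACATTCTACCAGAGTTTGAGAAATGATCTCACGCAGCCCAGGCACACAAATGAATGAATGAATGAATGAATGAATGAATGAGCTATCAGCCTTGTGCTATCACCTAAGGGCGTTACACGCCATACTCCCAGCGCGTTGAG,CAGGCACACA,AGCTATCAGC,4,0,8,,
vWA,CCTCGATACCGTACTAGGATCACGATTCTTTTGGTACATGGTACCAGTTCCAGAATCATTTCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTATCTACGGTTCCTAATGGCGAAGAGAATTTGGTTAACCGGTTATTACGTTGCGATGCTGAGCGCC,CAGAATCATT,CGGTTCCTAA,4,0,17,,
Amelogenin,ACCATCAACCTGTTTGTCCAAAACCTTATTCCACCCTGGGCGTACAAAGCCGCATGGGCGGTCAGTCCCAACCAAGGTCTATCTGGGGTCGGCACGTTTATCACATTCCCCGCAAAGAGTTCCCCG,CGCATGGGCG,CCCAACCAAG,6,0,1,,sex locus: no repeat; unit = 6 bp X/Y amplicon length difference; X=1 and Y=2 units
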