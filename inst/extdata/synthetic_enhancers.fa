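>msxb_B
TTGTATCTGATTATTCGTCCCTTTATATTTTAGACAACGTATTTATATTTTTTAAACAAACATGAGTACT
CTCTTTTACTGAATTATGGAATCTATGAATCTCTGTCTAAGATTCTAATAATATTAGATTAGTAATTTGC
AAGTCCAGCAACATTCTCTTTTAGATTGGATAGACCACTAATAAAAATCGTCGAACATGACTAAAATTTT
TTTTCTAATCATTGGGTGAACGATATGAAGACGTTGTCAGTCATGCAAAGAACAAACTTTCTA
>ci_msxb_line
TTGTATCTCTCGGTTCGTCCCTTTATATTTTCACCAACGGACATATATAATTAACGTTCCCATGAGTACT
CTCTTTTACTATGCCATGGAATCTATGAATCTCTACTGAAGATTCTAATAATATTACGCCGGTAATTTGC
TGAGGCTCCCGGATTATCTTTTAGATTGGAGACTTCACTAATAAAAGATTACATAATTGACTAAAAACAT
TTTTCCGTTTATAGACTGAAGAATATGACAAACAAACATCTTTGACAAAGTGATTACTTTCTATATTTTG
TCTGTCCAGGAACGGTTAATCTGCAACCGTCGCGTGTTTCAATTGGTTAAGCAGACGAAAAACGATAACG
ATTATAACCACATCGTCAGACTAAACGAAAATTCTGTTTTATGCTCTAAGTAGATTAATTTATTTTCTGG
AGACTAAGGTTCACTTCCATTGCTACATTGAATAAGAAACTGGTATGGAAGGATATTACTGTAATGAACG
GGATACGACAAAAGATAGAATCATATTTAAATTAAGCATAAGTCCCTTAGCTTGAGGGATAGTTACTGAA
ATTCGATCGGGCACTTTTTAACCTTGATCTTGGACCACAA
>ci_delta2_line
AATTAATAAATAGGCAAATTATTTTCCCTCACGATCTCGAGTTCTAATAAGGAACTCTTAATGTGAGCTA
AGATCTATTTTTCGTTATTCTACATAATGTGGATTATCGTATTTTTCTTGCAGACAATACGATATTATAA
AAACATGCTAAAGCGCAGTAGATTAGCGAGGTATAATTTAGTCTCCAAATAGAGCGACATAATCTCAGCT
GCTTATACCTGTTTTAAATGGTCCTGTACGATTAGAGCATAAGAGCAATAGACCTAACCCTCCACTTCAA
ACAGTATTGCCAAATACTGATTATATTAATTATTATAAAGATAGGATGTAGCGCGAAATCAATATTTCCC
GTGCTGCTGAATTGAATCTTTTTAAGATCGCTGGAATAGTAC
>pm_msxb_line
TGGCGATACTTTTACAGAATGCTAGATTTATCCAATACAAAATAAAATGAAGAGGTAGTTCTAGATTCGT
TAATTGCAATTACTAACCTCACAAGTTGTCCTTTTCATAATTGAAAAGTTAGTGAAAAAACTTCCATACC
GATCTTCATTGGATTACATGTACACACAGACTGCATTTGACTAAACAAACAACTAACGGTTCGATTAAAG
CTGAGAATAGACGTTTTTGTAACTGTTTTAATGAAATTTGATTAAACCATATTGTGTCTTTCTACATCAG
AAACAATCCCAATCATTAATCATAGTACTCATAGACATATAGGAGAATGTTTGCGTTATGTAAGATTAAC
CATATTTAAAGACGTTCAGCTTTGAAACAGCAAACTCAGTGATTAATATATTTACTAGACAGTATAAGAG
AGTCTATGGTAACCGAAAACAAGATTTAAGGCGTCCATCAACTAAATGAATCTTCATATCATGGTTACGT
ATTGGCCGCGGAGCATATTGGGGCCTAACGCAAAAAAGATATATATTACTATCTTTAACGTTTCCGTAAA
ACTCCCTAATGACAATCCTTAATTATT
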