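>synthetic_contig_1 random background
TCTCAGGAGCGATATTATGTCACTTAATACGTGACTGATCCGTCATTTCTTCAGACCTAAGTGGGTGGGG
GATCTACCCAGGCACATACCTGTGAGGTAATTCAGATACGTACGACTAACGGCGACCGAGTCACTACCTG
CGAGATTGGTTACTCGTTTGTGTTTCCTATCGTCCTCATCCTGAAAAGCCAGCATGCGCTCTGGAGTTAA
TATACCCAGATCGTAATTCTCATTCAGAACGGGATTTACTCGGACCGGACAGGACCATCCCGGCCAGTAG
GGCCCCTACCTAAACTAATTCTGGGTCTTTTACTCTTTACCAAAGGAGAGCTGTATTCCACGCTAATCTC
ACAATTAGTAATCGGTTCTTCTGGAATCTCCTGTGAGAGTACGAGATCGCCGGGTTCCGGCGCTTACGGC
GTTGGCGAAAGATTCGTATTTTACTTCTGGAGCCAGCGATTATCCGGATTCCGGTATCTCAGAACTTTCA
TCAACGCTGCCACAGAGGTTCACTCACTACTAGCGTGCACCGGTAGACGCATTGTGAGGGCACGGATCAG
TGGATGGTCTCATGGGCGCGCCTTGCTGGGTCCTATGTCT
>synthetic_contig_2 background plus 25 bp tandem repeat
TCTCAGGAGCGATATTATGTCACTTAATACGTGACTGATCCGTCATTTCTTCAGACCTAAGTGGGTGGGG
GATCTACCCAGGCACATACCTGTGAGGTAATTAAAACCTACAGGGATTAGTATCATTAAAACCTACAGGG
ATTAGTATCATTAAAACCTACAGGGATTAGTATCATTAAAACCTACAGGGATTAGTATCATTAAAACCTA
CAGGGATTAGTATCATTAAAACCTACAGGGATTAGTATCATTAAAACCTACAGGGATTAGTATCATTAAA
ACCTACAGGGATTAGTATCATTAAAACCTACAGGGATTAGTATCATTAAAACCTACAGGGATTAGTATCA
TTAAAACCTACAGGGATTAGTATCATTAAAACCTACAGGGATTAGTATCACTCTATAGCAATGGTTAGTA
CTCAAGACCCAGGATACTCAAGAGGGATGCGATAGTTGAGATAACGGCGATTTCCACCTGAGCAGATCCT
AAGCGTTCCT
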