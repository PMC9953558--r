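>chr6:142705865-142706619_synthetic_scaffold GRCh37 coordinates; printed primer/probe sequences embedded at assay geometry; filler bases random (seed 20230208); NOT the genomic reference sequence
TATCTTGTCTGTCAAGTCAGTTGGGCCGTCATGAGAAGGCTATGGAGCCAACGCGTTATC
AACGGATATCTTACTGGGGCAGATCCGTTTCTAAGCTCTTAGTTCGCGAGCTCACTGGAG
GCAGCCTACCGTCACATGGAACCTACATGCATGGATCAATACAAATCCTTGTTAGTGCAA
TACCGTAGTAGTGTTGGGCAAGTCCCATCGGAAGCCCGACCGAGCTACTTCACGTGATGT
TAGTGAATTAACAAGAGTAGCATACGTAGAGCTTCCAAATGAAATGGGAATATTATAATT
CTAACTAACGACCTCCGAGGATTGGCGACATCTATTTGTATGAACATACAAAGAGCCTCA
TGTCACACAAATTCCTCCCTCAGATCAAGAACATTTATACGGTGACAAACGGATCCCAAG
AGAGTCCCAACACCGGAAAGGAAAAATCTCATTTACTACTTATTAGGTGAACCAGTAAAG
ATAATCCTACCTTAGGTTGAAACGTACCGTTTGGGAAACTTTTTTATGAAACGGCGACCT
CGCCTGTCTTCGAGAAGTCACAACCGAGAGGGTTAAGCATTGACTGTGATGCGATTCATC
ACTCCTACCAAGGAACTTAGGCCCACCAAATCTGCCGGGAGCTGACGAGGTCATAACTCA
ATCAGGATGTGCGTCTCAGCGGCATCCGTGATTCGTAAAAAGGCTAGTAGTAATGTGGCA
GCGACGAATGGTCGTAGCCAGGTAATCTGTGACAC
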