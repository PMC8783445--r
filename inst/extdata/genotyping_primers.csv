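assay,name,role,sequence
CreER-Eyfp,common,common,AAGACTCACGTGGACCTGCT
CreER-Eyfp,wt_reverse,wt_reverse,AGGATGTTGACTTCCGAGTTG
CreER-Eyfp,mutant_reverse,mutant_reverse,CGGTTATTCAACTTGCACCA
CreER-Eyfp,long_target,long_target,TGTCCGTATAGGTTGGGAAA
DTA,common,common,AAAGTCGCTCTGAGTTGTTAT
DTA,wt_reverse,wt_reverse,GGAGCGGGAGAAATGGATATG
DTA,mutant_reverse,mutant_reverse,GCGAAGAGTTTGTCCTCAACC
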