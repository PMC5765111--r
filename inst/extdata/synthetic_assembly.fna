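>contig01 synthetic actinomycete-like assembly (simulated)
ACCGGATCGACGCTTACGGCCGCGGCAGTGCCTGCCAGGGGCCGGGGGGCTACGAGCCTGCTCCACGACG
AGCCCTAGCAGCCCACCACCCCAAGCGCGCTCGGCTGCAAAAGCGGAGGACGGGTGTACCGCGGGTTGAG
ATCCACGTCAGTGCGCGCGTCATCCAAATCCGATCCGGCCGGGCGTACGGCGGTTACTTCCCGACCCNAT
GGTGCGCGGCGCCACCTGACTACATGGGGCCCAGTCAGTCGGCTCCGAGACCCCGTCACATGCTGAGTGG
GAGCACCCTGCACAGACGCGCCGTTGCGCAGCCGCGGGCCCGCTCCAGCCCGTCGACCCCGCCGGCTATG
AGTAATCCGTCTCCTGAACGCTTGTGCCCCTACCACGGCAGGGCCGCCACCCTCACGCCCCGGTTACGCC
GTCACGCGGTGCACGCCGCAGTAAGAACCCCTTGCGCACGAAATCGACGGGCCACTTGCTGCCAGCGGCC
TCCAACACCGTAACCCGCGTCCATGCGGACAGCCGGCTTCCCGTCCTGAGCCCGCATGAACTGGTCCTTA
CCGCCGGACGNGGCCAGCATCCACGCACTGCGTCCCGGACCATGTTGGGGGCGCCGGGCCATGGGTCGGG
GCCCGGTGGCGCGGTGTGCGTCGTTATCCCGCCGCGCGAGCCTAACGGGGTCGGCCGGGACCCACTCCGA
TGAAGGGAGCTCGGAAATCGGCCGCCCCCGCACGATAAGCCCGCACCTCCGAGCCGCAACCTCACGCACT
GGAGCCCGGGTGCGCCCGAGCGGCAGCGGCGGTGCGGCTCCCCTCTCGAGCCACCCCGGCGAACGGACCG
CGGGAGNTGGCCGTCGGACCCTGACGCCTGTGACCCCAAGCGGCGACGGTAGACTTCCGG
>contig02 synthetic actinomycete-like assembly (simulated)
CCCCTCGCCATCCGCACCTGTCGGTATGTTCTCCGCCGGCCCTCCCGACATCCGACGTCGGCAGCCCCCG
GTCAAACAATGGCGGAGGCATAACCGCGGAGGGACTTGCCGCTTGTCTGGGGCCCGGCCGCGATGCGGGA
CGTACGCCGCAGCGTGCATCTGTGGTGCGCAGTCAGTCACGCCACCAGACTCTCNCCCGGTCGGTCATAT
GGCAGTCGGGCGCCACCAGGCCGCGTCCGCCTCGCACGCCGTCTGGGGGCACTGGCGATCCCACGGGCCC
GTGATGCAGCGGCCCTACGCCACCTCGACGGCGTCCTTCCTCTGCTGGCCACNATGCGCTCGTGAACGAG
GCGCCTGTAGCCCCGGTGCGGCCCTCGCCCCGCGTTCGTGGAGTTGCCCGGGGCTCCTCCAGCAGGGGGC
GAGGCGCGGTACGGCCCGATGGCGGAGCAAGGACCCAATCCAGGAGAGCGTGCGGGTGTCCGGGTGCGCA
TTGGTCCACAGGCGCCCCGCGCTCAGGGCGGTATGTGGGCCCCCGCTCCACACGCAATCACGGGTCAGCC
TAGAGCGGAAAGGTAGCGGGGCTGGCCGGCTGCCGCTTCCTTGTGTTAGACCGCAAGGGTTGCGGCTCGA
GCCCTGGGCTTGCGCCCTGGGTCAGAGGCCGCTGCCCNTCCCCGCCGCTGGCTGTTTGTCGGCCCGGCTC
>contig03 synthetic actinomycete-like assembly (simulated)
TCCACGGGGCTCCGCAGCGCAGCCCGTGTGCTGCCCTCCGAGAGATAGACACCGTCCCGCCTAGCATACC
TAGTTGACCCATCCCGTCGGCGCGCCGAGTNTCCCAGGGTACAGCGCGTCTGTAAAGCCTCGAGCGGTCT
GGGCAAGCCAGCCGGATAAGCCGCTCCTCGCGCCGTACGGTGGGTCGAGCCCGGCGCCGGGCGGCCGCCC
TGCGAGCCGGCCGTCCAGGCTCGGTTGCCTACGGCTTTTAANCGAGGGGCGCGTTTAGTGGGGGAGAAGG
CGCGACGGCCGTAGCCATCCTACCCCCCATCTNCATCCCCGGGCAAACAGGAGCGACGCCGGGACACGGA
GGTGGCGGCGGCAGATCACCGGGCCGCGGCGGGGTGGCGCCTGGGGGGGTGGATCCCCCGATCGCCGATC
GCCCGGCCCCGCTTGAGCCCTGGCTGACGGGCCGCCGGAGTCGCAGACCAGGCGGGTTCACCCAGGCGCG
CCCCCGAGTC
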