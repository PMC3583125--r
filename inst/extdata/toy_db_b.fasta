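>dbB_0001
CTCTTCTCTATAATTGAGGTAATCGGTATGTCACATTGAATCGTTGGGCCCAGCGAACGG
>dbB_0002
CTAGACGGCGCGTAGCGGTACCTGAATGTGGAGTCCATATTCAGCGCCAGATTCGAGTTT
>dbB_0003
TTTAAACTTCTTTGACTCTCATTGTAGATATGGGCCTGTATATGGTGTGTTATTTCATTT
>dbB_0004
AATCGGGTGAGCCCGTCGATGCGGATATTTTTTGCGAAATGGTGGATCTGAAACCGTTGA
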