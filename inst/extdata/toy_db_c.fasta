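>dbC_0001
CACAGTCTTTCTACGCTTATGGAATAGAAGCCAGAAACATGGGGCGGAGCTACTGTTCTC
>dbC_0002
GGTTGTAGACAGGAATCTTTTTTACTTTGGAGTCAGCGATCTCGATCCCCACTAGCGTGA
>dbC_0003
GTATGTTAAGTCTTACACCAATCCGAGCGTTATACTCTTTTCTGCTTATATGCCCGGTTC
>dbC_0004
GTTAGAACTAGGACTTGTGTTCGATACCGGGCAAGCCACATAAATGAGACTAGTAAGAGG
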