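>dbA_0001
GCGCAACAAAAGCCCATTAACTTCAGGATCCTGTGACAGGTGCAATCCTCACACCCCTCG
>dbA_0002
TGCCCGGCGATTGAATTTCTGGTCCGCAAAGAACTGAAACGTCATGTATCGGCATCCCCA
>dbA_0003
ATCCGGAATCTTCTAAAAAGCGTGGCCTAGCATCAAAGAGACCCGAACTCAGGTGCATTT
>dbA_0004
GTCCGACCGTAAAGAAATAGCGAGAACCTTTACCCTAGTCCAACTGGCATGGCGAGAATT
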