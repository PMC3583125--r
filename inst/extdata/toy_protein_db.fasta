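>dbP_0001
KQTDDKDDCYTQNAPGSLMYQIIYGHLLKFTNDKDLYCAP
>dbP_0002
SQNVRVTNCKLFQCVRFDMKLHYTIYLEEWKNPVHFIGWQ
>dbP_0003
SENDNNRFMRVYEKPMDHRWSVGAQMYWPITFFYKIPHQH
>dbP_0004
AFMSMFNMYATFQFKWKLNFYQEQWCLDGMAHWPSQCRYL
>dbP_0005
NSAVGMRIPPANRFAAYLNGKCSTCINHGFKSGFQIINVQ
>dbP_0006
TAMEEHDMARRQKGLPQKMWQYIRPRIKHQEDKEDARWWN
>dbP_0007
WEVHKYCIRQIIGSKLYKEKHAHSMRVGLLFPNLDNMRQS
>dbP_0008
PMLFVQWRNFTNGEYWCTFMKPIYKVRPQPPNVNRKQMHV
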