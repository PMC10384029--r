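>mg1
ATGGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTGCTTAA
>mg2
ATGAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATAACAATTAA
>mg3
ATGAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCAACAATCCTCCCTAA
>mg4
ATGATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATTATCATCATCATCATCATCATCATCATCATCATCATCATCATCATCATCATCATCATCATCTAA
>mg5
ATGGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACGCGTTCTACTAA
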