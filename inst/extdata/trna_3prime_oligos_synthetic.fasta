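>tRNA-iMet_3prime_18mer synthetic
GGGCTCGTTGGTCTACCA
>tRNA-Lys_3prime_18mer synthetic
TTATCGGCTTCACTGCCA
>tRNA-Arg_3prime_18mer synthetic
GTTCCGCCACCTCGCCCA
>tRNA-Trp_3prime_18mer synthetic
TGCATGCGGACGTTGCCA
>tRNA-Gly_3prime_18mer synthetic
TACGCTGGACCAAGGCCA
>tRNA-Leu_3prime_18mer synthetic
TAAATCCATCAGAACCCA
>tRNA-Ser_3prime_18mer synthetic
ACGTGGTTCCGGAACCCA
>tRNA-Asn_3prime_18mer synthetic
TACACCCTCGATGGCCCA
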