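>site1
tgtctatgctcag
>site2
cttttgtgctgtt
>site3
ccaaactgctgac
>site4
cgtaactgctgac
>site5
caaatttgcagac
>site6
taaagttgctgaa
>site7
catttctgctgac
>site8
aggatgtgatgac
>site9
tgttgttgctcac
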