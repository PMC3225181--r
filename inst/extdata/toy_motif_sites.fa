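>site1
TGACTCAT
>site2
TGACTCAT
>site3
TGACTCTT
>site4
TGACTCAT
>site5
TGACTCCT
>site6
TGGCTCAT
>site7
TGACTCAT
>site8
TGCCTCAT
>site9
TGTCTCAT
>site10
TGATTCAT
>site11
TGACTCCT
>site12
TGACTCAT
>site13
TGACTCAT
>site14
TGAATCAT
>site15
TGACTCAT
>site16
TGACTCAT
>site17
TGACTCAC
>site18
TGACCCAT
>site19
TTACTCAT
>site20
TGACTCAT
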