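# Shared alphabet constants (file sorts first so later files can use them
# at load time).
DNA_BASES <- c("A", "C", "G", "T")

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")
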