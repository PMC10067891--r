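# n=7 d=5 W=3 constraints=gc,nl,rc
# example 23-word coding set at n=7, d=5 (as published)
CTGTGAC
ATGTACG
CATCTGC
GCAATCT
AGACATG
GTCTGAC
TAGCCTA
TCAGTCA
GAGATTC
GTACTAT
GATGCTA
CTGCCTC
GAATGCT
TACGCAG
GTACGAT
ACTGACA
CTACGAT
GTGACAC
CATCGAG
GGCACTA
ACGAGTC
TGTTACG
TGAACTG
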