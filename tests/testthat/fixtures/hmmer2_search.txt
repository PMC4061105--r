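hmmsearch - search a sequence database with a profile HMM
HMMER 2.3.2 (Oct 2003)

Alignments of top-scoring domains:
t1: domain 1 of 1, from 3 to 17: score 44.9, E = 6.1e-16
                   *->MKVLITGAGSGIGlE<-*
                      MKVLITGAGSGIGLE
        t1     3      MKVLITGAGSGIGLE    17

t2: domain 1 of 1, from 1 to 19: score 33.5, E = 2.4e-12
                   *->MKVLIT....GAGSGIGlE<-*
                      MKVLIT    GAGSGIG+E
        t2     1      MKVLITaaaaGAGSGIGKE    19

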