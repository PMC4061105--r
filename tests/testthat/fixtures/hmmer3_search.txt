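# hmmsearch :: search profile(s) against a sequence database
# HMMER 3.4 (Aug 2023); http://hmmer.org/
# Copyright (C) 2023 Howard Hughes Medical Institute.
# Freely distributed under the BSD open source license.
# - - - - - - - - - - - - - - - - - - - - - - - - - - - - - - - - - - - -
# query HMM file:                  toy.hmm
# target sequence database:        target.fa
# sequence reporting threshold:    E-value <= 10
# biased composition HMM filter:   off
# null2 bias corrections:          off
# - - - - - - - - - - - - - - - - - - - - - - - - - - - - - - - - - - - -

Query:       toy.aln  [M=15]
Scores for complete sequences (score includes all domains):
   --- full sequence ---   --- best 1 domain ---    -#dom-
    E-value  score  bias    E-value  score  bias    exp  N  Sequence Description
    ------- ------ -----    ------- ------ -----   ---- --  -------- -----------
    5.4e-16   45.0   0.0    6.1e-16   44.9   0.0    1.1  1  t1        
    4.2e-13   35.9   0.0    2.4e-12   33.5   0.0    1.8  1  t2        


Domain annotation for each sequence (and alignments):
>> t1  
   #    score  bias  c-Evalue  i-Evalue hmmfrom  hmm to    alifrom  ali to    envfrom  env to     acc
 ---   ------ ----- --------- --------- ------- -------    ------- -------    ------- -------    ----
   1 !   44.9   0.0   6.1e-16   6.1e-16       1      15 []       3      17 ..       3      17 .. 0.99

  Alignments for each domain:
  == domain 1  score: 44.9 bits;  conditional E-value: 6.1e-16
  toy.aln  1 MKVLITGAGSGIGlE 15
             MKVLITGAGSGIGlE
       t1  3 MKVLITGAGSGIGLE 17
             **************9 PP

>> t2  
   #    score  bias  c-Evalue  i-Evalue hmmfrom  hmm to    alifrom  ali to    envfrom  env to     acc
 ---   ------ ----- --------- --------- ------- -------    ------- -------    ------- -------    ----
   1 !   33.5   0.0   2.4e-12   2.4e-12       1      15 []       1      19 []       1      19 [] 0.99

  Alignments for each domain:
  == domain 1  score: 33.5 bits;  conditional E-value: 2.4e-12
  toy.aln  1 MKVLIT....GAGSGIGlE 15
             MKVLIT    GAGSGIG+E
       t2  1 MKVLITaaaaGAGSGIGKE 19
             ******************9 PP



Internal pipeline statistics summary:
-------------------------------------
Query model(s):                            1  (15 nodes)
Target sequences:                          2  (38 residues searched)
Passed MSV filter:                         2  (1); expected 0.0 (0.02)
Passed bias filter:                        2  (1); expected 0.0 (0.02)
Passed Vit filter:                         2  (1); expected 0.0 (0.001)
Passed Fwd filter:                         2  (1); expected 0.0 (1e-05)
Initial search space (Z):                  2  [actual number of targets]
Domain search space  (domZ):               2  [number of targets reported over threshold]
# CPU time: 0.00u 0.00s 00:00:00.00 Elapsed: 00:00:00.00
# Mc/sec: 0.70
//
[ok]
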