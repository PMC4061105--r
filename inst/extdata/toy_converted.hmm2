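HMMER2.0  [converted from 3.4]
NAME  toy.aln
LENG  15
ALPH  Amino
RF    no
CS    no
MAP   yes
NSEQ  5
DATE  Sun Sep 20 17:40:09 2026
XT       -8455     -4  -1000  -1000  -8455     -4  -8455     -4
NULT        -4  -8455
NULE       656  -1722     98    419   -333    475  -1125    239    250    947  -1073   -271    -50   -338    114    451    113    430  -2131   -717
HMM        A      C      D      E      F      G      H      I      K      L      M      N      P      Q      R      S      T      V      W      Y    
         m->m   m->i   m->d   i->m   i->i   d->m   d->d   b->m   m->e
           -3      *  -8756
     1   -3517  -3087  -4591  -4762  -2557  -3860  -3865  -2307  -4294  -1753   5236  -4203  -4196  -4159  -4141  -3858  -3567  -2698  -3302  -3163     1
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378    -10      *
     2   -2831  -3197  -3590  -2164  -4254  -3243  -1106  -3616   3405  -3233  -2553  -1792  -3124   -632   2036  -2566  -2330  -3407  -2856  -2868     2
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
     3   -2586  -2154  -4551  -4636  -2833  -3724  -4130   -338  -4410  -2011  -1917  -3939  -4052  -4276  -4384  -3338  -2600   3670  -3727  -3471     3
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
     4    1117  -1821  -3976  -3835  -1409  -3088  -3030   -758  -3420   2745   -405  -3079  -3376  -3026  -3351  -2331  -1983  -1072  -2565  -2438     4
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
     5   -2328  -1622  -4920  -4661  -2267  -4680  -4580   3399  -4497  -1133  -1054  -4231  -4422  -4360  -4674  -3938  -2176   1915  -3822  -3415     5
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
     6   -2142  -2334  -3805  -4128  -4168  -2734  -3703  -4014  -3974  -4319  -3777  -3162  -3379  -3805  -3892  -2258   4064  -3366  -3996  -4130     6
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
     7   -3743  -3431  -4403  -4828  -5243   3790  -4453  -5952  -5073  -5716  -5301  -4289  -4195  -4826  -4836  -3873  -3982  -5171  -4292  -5142     7
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
     8    3135   3428  -4015  -4266  -3671  -1862  -3339  -3205  -3846  -3714  -2910  -2463  -2591  -3396  -3636  -1136  -1311  -2384  -3864  -3807     8
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
     9   -3743  -3431  -4403  -4828  -5243   3790  -4453  -5952  -5073  -5716  -5301  -4289  -4195  -4826  -4836  -3873  -3982  -5171  -4292  -5142     9
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
    10   -1704  -2008  -3333  -3695  -4038  -2378  -3443  -4349  -3791  -4503  -3736  -2730  -3065  -3487  -3760   3700  -1999  -3329  -3957  -3885    10
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
    11   -3743  -3431  -4403  -4828  -5243   3790  -4453  -5952  -5073  -5716  -5301  -4289  -4195  -4826  -4836  -3873  -3982  -5171  -4292  -5142    11
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
    12   -2770  -2053  -5175  -4803  -1333  -4897  -4068   3348  -4501   1326   -195  -4441  -4391  -3837  -4371  -4135  -2564     -2  -2901  -2853    12
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
    13   -3743  -3431  -4403  -4828  -5243   3790  -4453  -5952  -5073  -5716  -5301  -4289  -4195  -4826  -4836  -3873  -3982  -5171  -4292  -5142    13
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
    14   -1878  -2341  -2055  -1405  -2582  -2667   -979  -2216   1719   2024  -1496  -1272  -2650   2009    -59  -1740  -1572  -2125  -2381  -2113    14
     -    -210   -336    220    -37   -342    377     73   -669    210   -511   -732    404    423     70     27    439    205   -414   -161   -176
     -     -10  -7714  -8756   -894  -1115   -701  -1378      *      *
    15   -3838  -3962  -1938   3791  -4946  -3377  -3157  -5421  -3371  -5200  -4808  -2483  -3846  -2982  -3830  -3550  -3828  -5006  -4224  -4390    15
     -       *      *      *      *      *      *      *      *      *      *      *      *      *      *      *      *      *      *      *      *
     -       *      *      *      *      *      *      *      *      0
//
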