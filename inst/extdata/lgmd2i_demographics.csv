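participant,sex,age_years,bmi,onset_age_years,allele1,allele2,ck_UL
1,F,38,21.2,29,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),2423
2,F,53,21.0,22,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),488
3,M,51,27.9,38,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),5668
4,F,38,21.1,28,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),951
5,F,65,26.6,35,c.826C>A (p.Leu276Ile),c.1073C>T (p.Pro358Leu),202
6,F,33,20.3,22,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),1506
7,M,41,16.1,25,c.826C>A (p.Leu276Ile),c.1433T>C (p.Ile478Thr),2832
8,F,26,27.0,20,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),4579
9,F,23,15.0,15,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),2399
10,M,30,22.3,26,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),981
11,M,67,24.5,40,c.826C>A (p.Leu276Ile),c.586G>C (p.Gly196Arg),226
12,F,23,23.0,17,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),1726
13,M,34,21.5,20,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),3983
14,F,41,30.3,21,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),3072
15,F,47,27.1,16,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),222
16,M,32,21.7,14,c.826C>A (p.Leu276Ile),c.1087G>T (p.Val363Leu),1716
17,F,44,20.2,15,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),1099
18,F,29,24.8,18,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),1428
19,M,19,27.6,5,c.826C>A (p.Leu276Ile),c.826C>A (p.Leu276Ile),4803
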