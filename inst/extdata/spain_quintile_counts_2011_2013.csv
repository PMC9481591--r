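sex,year,quintile,deaths,population
male,2011,Q1,35217,5256845
male,2011,Q2,39405,5073220
male,2011,Q3,41134,4759007
male,2011,Q4,39745,4270710
male,2011,Q5,39523,3921491
male,2012,Q1,36126,5288462
male,2012,Q2,40656,5075266
male,2012,Q3,42394,4750182
male,2012,Q4,41073,4254020
male,2012,Q5,40949,3888492
male,2013,Q1,35551,5272262
male,2013,Q2,39766,5039926
male,2013,Q3,40643,4703703
male,2013,Q4,39752,4194731
male,2013,Q5,39314,3832194
female,2011,Q1,38283,5657980
female,2011,Q2,37608,5270843
female,2011,Q3,37515,4853180
female,2011,Q4,35979,4277989
female,2011,Q5,34734,3845162
female,2012,Q1,39696,5699851
female,2012,Q2,39340,5286365
female,2012,Q3,39459,4854909
female,2012,Q4,37451,4268555
female,2012,Q5,37020,3815310
female,2013,Q1,38846,5691572
female,2013,Q2,38137,5266307
female,2013,Q3,38004,4824427
female,2013,Q4,36221,4224892
female,2013,Q5,35242,3772367
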