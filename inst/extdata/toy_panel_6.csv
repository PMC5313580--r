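person_id,year,insurer_id,sex,expenses
1,2008,1,M,0
2,2008,1,F,400
3,2008,2,F,2500
4,2008,2,M,100
5,2008,1,M,900
6,2008,2,F,300
1,2009,2,M,150
2,2009,1,F,350
3,2009,1,F,3000
4,2009,2,M,0
5,2009,2,M,700
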