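"person_id","year","insurer_id","age_band","sex","region","chronic","unpriced_effect","expenses"
1,2008,1,"35-54","M","west","yes",0,7065.20665898541
2,2008,2,"55-69","M","east","yes",0,70.7662828705405
3,2008,3,"35-54","F","east","no",0,0
4,2008,1,"35-54","M","west","yes",0,959.37281633464
5,2008,1,"18-34","F","east","no",0,953.167009521831
6,2008,3,"35-54","F","south","no",0,58.8905101259782
7,2008,2,"35-54","M","north","no",0,0
8,2008,1,"55-69","F","north","yes",0,166.959919691829
9,2008,1,"0-17","F","south","no",0,13.911918754127
10,2008,3,"35-54","M","north","no",0,10.335046246028
11,2008,1,"0-17","M","west","yes",0,2040.45151575954
12,2008,1,"55-69","M","east","yes",0,4209.89688744829
13,2008,1,"0-17","M","north","no",0,106.550747206763
14,2008,3,"70+","M","north","no",0,0
15,2008,3,"18-34","M","south","no",0,0
16,2008,1,"55-69","F","west","no",0,1781.78951441605
17,2008,2,"55-69","F","west","yes",0,17313.89601591
18,2008,3,"18-34","M","east","no",0,141.908570257907
19,2008,2,"0-17","M","west","no",0,0
20,2008,3,"70+","F","east","no",0,1233.06479908523
21,2008,2,"35-54","F","north","no",0,75.2679814801278
22,2008,2,"0-17","F","south","no",0,294.299794580076
23,2008,1,"0-17","M","east","yes",0,1874.43865337278
24,2008,3,"18-34","F","north","yes",0,2437.2267214554
25,2008,2,"18-34","M","west","no",0,1708.61472258689
26,2008,3,"35-54","M","north","no",1412.39140035205,0
27,2008,2,"35-54","M","north","no",898.933856087102,159.451119293104
28,2008,1,"35-54","M","east","yes",1393.06837062072,4937.42923466814
29,2008,2,"0-17","M","east","no",0,0
30,2008,1,"18-34","F","north","no",0,370.982122917179
31,2008,2,"55-69","M","west","no",0,2727.24649716787
32,2008,1,"55-69","F","east","no",0,870.843872620509
33,2008,1,"0-17","M","west","yes",0,212.816445991191
34,2008,3,"18-34","M","south","no",0,636.991979789679
35,2008,1,"0-17","M","west","no",562.119390380808,1682.40864521886
36,2008,2,"35-54","M","east","no",0,116.986051330012
37,2008,3,"18-34","M","north","no",0,1102.70053198411
38,2008,3,"55-69","F","east","no",0,1760.59204118562
39,2008,1,"0-17","F","west","no",0,0
40,2008,2,"35-54","M","north","no",0,782.743908275509
41,2008,2,"18-34","M","north","no",0,1241.30677351721
42,2008,2,"18-34","M","west","no",0,9.74043105865901
43,2008,3,"18-34","F","east","no",0,0
44,2008,3,"55-69","M","north","no",0,422.978630602439
45,2008,1,"0-17","M","east","no",0,214.037793130368
46,2008,2,"35-54","F","south","no",1276.86776846402,1635.45163169994
47,2008,3,"18-34","M","east","yes",0,1250.65931132397
48,2008,1,"55-69","M","east","yes",607.366260951521,11788.890774359
49,2008,3,"55-69","M","south","yes",0,8930.66731621067
50,2008,1,"55-69","M","west","no",0,0
1,2009,3,"35-54","M","west","yes",0,888.249017552262
2,2009,2,"55-69","M","east","yes",0,1408.61801817426
3,2009,3,"35-54","F","east","no",0,1274.73841414595
4,2009,1,"35-54","M","west","yes",0,4577.5419183706
5,2009,1,"18-34","F","east","no",0,248.460236261424
6,2009,3,"35-54","F","south","no",0,1935.91645651918
7,2009,2,"35-54","M","north","no",0,1684.68009829343
8,2009,1,"55-69","F","north","yes",0,4299.03285538248
9,2009,1,"0-17","F","south","no",0,659.684944780319
10,2009,3,"35-54","M","north","no",0,98.2982098736565
11,2009,1,"0-17","M","west","yes",0,1628.76377801535
12,2009,1,"55-69","M","east","yes",0,721.750799509474
13,2009,1,"0-17","M","north","no",0,44.7729875761118
14,2009,3,"70+","M","north","no",0,0
15,2009,2,"18-34","M","south","no",0,10.3504238821844
16,2009,1,"55-69","F","west","no",0,826.451497123422
17,2009,1,"55-69","F","west","yes",0,3199.34714904096
18,2009,3,"18-34","M","east","no",0,1447.81436289544
19,2009,2,"0-17","M","west","no",0,5.38136332449061
20,2009,3,"70+","F","east","no",0,1105.47324768535
21,2009,1,"35-54","F","north","no",0,557.859921344366
22,2009,2,"0-17","F","south","no",0,176.432485201285
23,2009,1,"0-17","M","east","yes",0,0
24,2009,1,"18-34","F","north","yes",0,875.20170719199
25,2009,2,"18-34","M","west","no",0,0
26,2009,3,"35-54","M","north","no",1412.39140035205,0
27,2009,2,"35-54","M","north","no",898.933856087102,1145.75822244673
28,2009,1,"35-54","M","east","yes",1393.06837062072,2535.00414229008
29,2009,1,"0-17","M","east","no",0,162.572529676226
30,2009,1,"18-34","F","north","no",0,130.729596227885
31,2009,2,"55-69","M","west","no",0,725.277025594272
32,2009,1,"55-69","F","east","no",0,121.734772740298
33,2009,1,"0-17","M","west","yes",0,861.028649135311
34,2009,3,"18-34","M","south","no",0,0
35,2009,1,"0-17","M","west","no",562.119390380808,1653.13741557276
36,2009,2,"35-54","M","east","no",0,0
37,2009,3,"18-34","M","north","no",0,50.3420449784442
38,2009,3,"55-69","F","east","no",0,645.732482015116
39,2009,1,"0-17","F","west","no",0,0
40,2009,3,"35-54","M","north","no",0,0
41,2009,2,"18-34","M","north","no",0,0
42,2009,2,"18-34","M","west","no",0,0
43,2009,2,"18-34","F","east","no",0,24.008092058573
44,2009,3,"55-69","M","north","no",0,55.1600549432022
45,2009,1,"0-17","M","east","no",0,0
46,2009,2,"35-54","F","south","no",1276.86776846402,4226.87007507306
47,2009,3,"18-34","M","east","yes",0,177.732536840677
48,2009,1,"55-69","M","east","yes",607.366260951521,2915.01004900687
49,2009,3,"55-69","M","south","yes",0,457.53520235744
50,2009,1,"55-69","M","west","no",0,749.816460247575
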