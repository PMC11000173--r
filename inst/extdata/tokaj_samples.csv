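sample_id,producer,category,vintage,set_label
1,J&J Ostrožovič,Selection essence,2017,C
2,J&J Ostrožovič,Selection essence diluted 2:1,2017,C
3,Tokaj & Co.,Samorodné dry,2015,C
4,Tokaj & Co.,5-Putňa selection,2015,C
5,Tokaj & Co.,Samorodné dry,2011,C
6,Nagy,Zeta,2011,C
7,Tokaj & Co.,Lipovina,2015,C
8,Tokaj & Co.,Muscat yellow,2015,P
9,Tokaj & Co.,Tokaj forditáš,2011,P
10,Tokaj & Co.,4-Putňa selection,2009,P
11,Tokaj & Co.,6-Putňa selection,2006,C
12,Tokaj & Co.,Selection essence,2009,P
13,Tokaj & Co.,6-Putňa selection,2011,C
14,Tokaj & Co.,6-Putňa selection,2011,C
15,Tokaj & Co.,Samorodné dry,2011,C
16,Nagy,Muscat yellow,2013,C
17,Nagy,3-Putňa selection,2006,C
18,Nagy,Lipovina,2013,C
19,Nagy,6-Putňa selection,2009,C
20,Tokaj & Co.,2-Putňa selection,1989,C
21,J&J Ostrožovič,3-Putňa selection,1999,C
22,J&J Ostrožovič,6-Putňa selection,1993,C
23,J&J Ostrožovič,Selection essence,2000,P
24,Zlatý Strapec,5-Putňa selection,1993,P
25,Zlatý Strapec,6-Putňa selection,1993,P
26,Zlatý Strapec,4-Putňa selection,1993,C
27,Zlatý Strapec,3-Putňa selection,1995,C
28,Zlatý Strapec,4-Putňa selection,2000,C
29,Zlatý Strapec,Samorodné dry,1997,C
30,Tokaj & Co.,Samorodné sweet,1997,C
31,Tokaj & Co.,2-Putňa selection,1990,C
32,Tokaj & Co.,6-Putňa selection,1993,P
33,Tokaj & Co.,Selection essence,1999,P
34,Tokaj & Co.,4-Putňa selection,1995,C
35,J&J Ostrožovič,4-Putňa selection,1993,C
36,J&J Ostrožovič,4-Putňa selection,2002,P
37,J&J Ostrožovič,6-Putňa selection,1999,C
38,J&J Ostrožovič,5-Putňa selection,1993,C
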