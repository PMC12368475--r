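animal_id,age_class,sex,body_mass_kg,origin,trials_almond,trials_gummy_bear,trials_peanut,trials_popcorn,trials_sunflower_seed
1,OLDER_JUVENILE,M,1.75,SEMI_WILD,5,2,5,6,7
2,OLDER_JUVENILE,M,1.6,SEMI_WILD,5,2,7,5,3
3,JUVENILE,M,1.94,SEMI_WILD,3,3,5,5,5
4,SUBADULT_ADULT,F,2.11,SEMI_WILD,5,2,5,5,5
5,JUVENILE,F,1.25,SEMI_WILD,0,2,2,0,2
12,JUVENILE,M,1.6,SEMI_WILD,5,2,4,5,5
14,JUVENILE,M,1.42,SEMI_WILD,5,2,5,5,5
15,JUVENILE,F,1.2,SEMI_WILD,4,2,2,1,0
16,OLDER_JUVENILE,F,1.9,SEMI_WILD,4,2,4,3,4
17,INFANT,M,1.1,SEMI_WILD,4,2,5,0,5
18,INFANT,F,1.14,SEMI_WILD,3,2,2,1,4
19,JUVENILE,M,1.57,SEMI_WILD,4,2,4,4,5
20,SUBADULT_ADULT,F,2.12,SEMI_WILD,4,2,4,4,5
21,SUBADULT_ADULT,F,2.13,SEMI_WILD,4,2,4,2,4
22,SUBADULT_ADULT,M,3.5,SEMI_WILD,4,2,4,4,5
23,SUBADULT_ADULT,M,3.5,SEMI_WILD,2,2,4,3,5
24,SUBADULT_ADULT,M,3.5,SEMI_WILD,5,2,5,5,5
25,SUBADULT_ADULT,M,3.5,SEMI_WILD,3,2,4,4,2
26,SUBADULT_ADULT,M,3.5,SEMI_WILD,5,2,5,5,5
27,JUVENILE,F,1.35,SEMI_WILD,3,1,1,1,1
28,JUVENILE,M,1.93,SEMI_WILD,4,0,5,5,5
30,JUVENILE,F,1.45,SEMI_WILD,3,2,4,3,5
31,JUVENILE,F,1.19,SEMI_WILD,5,1,4,5,1
32,JUVENILE,F,1.54,SEMI_WILD,3,2,5,5,4
33,OLDER_JUVENILE,F,1.9,SEMI_WILD,5,3,8,4,3
34,JUVENILE,F,1.75,SEMI_WILD,5,0,0,0,0
95,SUBADULT_ADULT,M,3.35,CAPTIVE,5,3,5,5,4
98,SUBADULT_ADULT,M,3.95,CAPTIVE,0,0,0,1,5
99,SUBADULT_ADULT,M,3.2,CAPTIVE,5,3,5,2,4
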