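id,necrosis_group,sex,age,surgery,initial_therapy,chemo_with_bev
1,plus,M,27,R,XRT/Tem,CCNU
2,plus,M,56,R,XRT/Tem,None
3,plus,M,37,Biopsy,XRT/Tem,None
4,plus,M,53,GTR,"XRT, Tem",Tem
5,plus,M,43,Biopsy,"XRT/Tem, ICT-107",None
6,plus,M,47,GTR,"Gliadel, XRT/Tem",CCNU
7,plus,M,55,GTR,"XRT/Tem, R-(-)-gossypol",CPT-11
8,plus,M,53,GTR,XRT/Tem,None
9,plus,F,50,R,"XRT, Tem",Tem
10,plus,F,44,Biopsy,XRT/Tem,CCNU
11,plus,F,73,STR,XRT/Tem,CCNU
12,minus,M,57,STR,XRT/Tem,CPT-11
13,minus,M,65,GTR,XRT/Tem,CPT-11
14,minus,M,29,STR,XRT/Tem,CCNU + Etoposide
15,minus,M,54,STR,"XRT, Tem",CCNU
16,minus,M,61,STR,XRT/Tem,Tem
17,minus,M,53,STR,XRT/Tem,CPT-11
18,minus,M,63,STR,XRT/Tem,None
19,minus,M,53,GTR,XRT/Tem,Tem
20,minus,M,38,GTR,XRT/Tem,CPT-11
21,minus,M,65,STR,"Gliadel, XRT/Tem",Tem
22,minus,F,58,R,XRT/Tem,None
23,minus,F,60,STR,XRT/Tem,None
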