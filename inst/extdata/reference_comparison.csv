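no,name,esm,qams,smd
1,Rg1,53.85,53.80,0.10
2,Re,151.28,143.83,4.92
3,Rf,29.34,29.47,0.46
4,Rb1,324.15,316.05,2.50
5,Rg2,29.22,30.21,3.38
6,Rh1,1.39,1.35,2.54
7,Rc,97.77,96.82,0.97
8,F1,0.55,0.57,2.52
9,Rb2,112.03,112.03,NA
10,Rb3,17.94,17.88,0.38
11,Rd,97.66,98.03,0.38
12,GXVII,2.56,2.54,0.91
13,nFe,3.92,3.71,5.33
14,CO,2.22,2.20,0.52
15,nFd,1.75,1.76,0.50
16,F2,1.25,1.24,0.71
17,G75,0.11,0.10,5.45
18,Rg3,2.95,2.86,3.05
19,PPT,1.03,1.01,1.53
20,Mc,0.91,0.88,3.69
21,CY,2.42,2.42,0.21
22,CMx,0.38,0.37,1.40
23,CK,1.42,1.41,0.18
24,Rh2,0.33,0.32,4.12
25,PPD,0.47,0.46,2.09
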