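# Characteristics and laboratory data of the 29-patient nephrotic cohort.
# Units: age years; u_protein g/day; tp, albumin g/dL; bun, creatinine mg/dL;
# egfr mL/min/1.73m2; igg, iga, igm mg/dL. Empty cell = not recorded.
patient_id,age,sex,biopsy,association,u_protein,tp,albumin,bun,creatinine,egfr,igg,iga,igm
1,47,F,Not done,SLE,2.1,4.5,1.3,9.4,0.41,126,447,597,75
2,37,F,MCNS,,4.1,5.5,1.9,12.6,0.48,114,1677,264,125
3,55,M,Not done,Rectal cancer,5.2,5.2,2.1,11.6,0.58,111,1020,190,86
4,61,F,endo-GN,,9.6,5.0,1.8,12.4,0.59,78,818,336,115
5,32,F,endo-GN,,7.6,4.6,1.9,13.5,0.71,77,715,346,103
6,70,M,MN,,7.0,5.7,2.9,12.0,0.77,76,712,264,92
7,71,F,MCNS,,10.2,5.2,2.4,17.2,0.65,68,633,270,85
8,61,M,MCNS,,14.3,4.8,1.0,21.9,0.92,65,1011,687,111
9,76,F,MCNS,,10.7,3.9,0.9,34.8,0.73,58,746,154,36
10,65,M,MCNS,,3.7,4.8,1.4,11.6,1.01,58,542,546,144
11,81,F,FSGS,,7.0,5.5,2.8,25.5,0.75,56,541,165,45
12,78,F,MCNS,,4.8,4.4,1.8,11.1,0.81,52,366,218,87
13,75,M,MCNS,,10.7,3.6,1.1,33.5,1.10,51,422,244,33
14,89,F,Not done,,4.2,4.7,2.4,16.4,0.81,50,687,203,58
15,70,M,MN,,8.0,5.6,2.9,18.9,1.20,47,633,241,43
16,60,M,Not done,Thrombocytosis,11.0,4.5,1.9,18.7,1.46,40,866,224,40
17,60,M,FSGS,,18.2,3.5,0.9,37.2,1.72,33,467,412,114
18,81,M,MN,,5.7,4.2,1.8,25.4,1.61,33,604,224,74
19,87,F,Not done,MN suspected,6.5,4.6,1.8,24.2,1.20,33,734,529,21
20,71,F,Not done,MCNS suspected,12.3,4.4,1.4,78.0,1.38,30,362,314,123
21,86,M,Not done,MCNS suspected,3.9,4.1,0.8,27.9,1.76,29,1590,488,39
22,71,M,Not done,"RA, bucillamine",7.5,5.1,2.1,45.8,1.97,27,883,60,104
23,54,M,Not done,DM,12.0,3.9,1.5,16.8,2.56,22,311,156,38
24,76,F,Not done,,17.3,5.5,1.0,20.5,2.02,19,2755,414,42
25,76,M,Not done,AL amyloidosis,4.6,4.1,1.8,46.0,3.57,14,647,48,19
26,77,F,Crescentic GN,,3.6,5.4,1.8,45.7,3.77,10,1290,285,42
27,82,M,Not done,DM,7.8,5.4,2.4,69.8,5.12,9,1022,192,58
28,74,F,Crescentic GN,,4.8,5.5,2.0,70.9,4.13,9,1146,362,52
29,70,F,Not done,MPO-ANCA,3.9,5.3,1.9,69.3,5.64,6,2285,636,108
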