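# Arterial blood gas panel for the 29-patient nephrotic cohort.
# Units: paco2, pao2, aado2 Torr; hco3, ag, cag mEq/L; lactate mmol/L.
# aado2 is a recorded input (analyzer output), never recomputed.
# ag and cag are the reported gap columns; the package recomputes cag from
# ag and albumin as a transcription guard.
patient_id,ph,paco2,pao2,hco3,aado2,ag,cag,lactate
1,7.43,34.0,70.3,22.1,46.8,8.9,16.7,1.3
2,7.48,25.7,110.6,18.9,16.9,11.1,17.4,0.6
3,7.46,34.1,128.3,23.7,79.9,8.3,14.1,1.2
4,7.44,38.7,82.8,26.0,28.4,6.0,12.5,2.1
5,7.45,36.4,106.6,24.8,7.5,5.2,11.5,1.0
6,7.45,35.0,47.3,24.0,68.6,7.0,10.8,1.6
7,7.43,37.4,83.3,24.4,29.6,8.6,13.6,0.9
8,7.44,35.1,98.3,23.5,17.4,7.5,16.0,3.3
9,7.55,27.9,66.6,24.2,58.1,10.8,19.6,2.4
10,7.43,43.2,84.2,28.2,21.4,7.8,15.3,1.8
11,7.34,34.9,85.5,21.2,30.5,11.8,15.8,4.2
12,7.43,41.3,75.7,28.0,32.3,6.0,12.5,0.9
13,7.42,40.8,67.2,25.9,41.4,5.1,13.4,1.5
14,7.56,29.4,92.2,26.1,30.7,9.9,14.9,1.3
15,7.42,42.1,83.6,26.8,23.4,9.2,13.0,1.0
16,7.36,40.0,56.0,22.4,53.6,9.6,15.9,2.6
17,7.47,33.1,80.4,23.7,37.8,7.3,16.1,1.4
18,7.45,36.9,84.8,24.9,28.7,7.1,13.6,0.9
19,7.43,43.9,99.5,28.6,5.2,7.4,13.9,3.8
20,7.42,41.3,59.3,26.1,48.7,9.9,17.4,1.5
21,7.49,28.4,114.4,21.1,100.9,6.9,15.9,1.2
22,7.42,32.0,94.1,20.6,25.5,13.4,19.2,1.7
23,7.43,44.6,62.7,29.4,41.2,5.6,12.9,1.0
24,7.45,30.8,52.4,20.9,68.7,6.1,14.6,1.2
25,7.45,31.9,125.4,21.9,55.1,10.1,16.6,1.2
26,7.48,26.5,77.9,19.3,48.6,13.7,20.2,1.0
27,7.29,31.5,87.9,14.9,32.3,14.1,19.1,0.9
28,7.32,28.7,111.5,14.1,73.0,16.9,22.9,1.9
29,7.40,21.5,98.8,13.1,33.9,16.9,23.2,1.9
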