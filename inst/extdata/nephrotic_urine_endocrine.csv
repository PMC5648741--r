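# Plasma/urine osmolarity, urinary electrolytes, plasma renin activity (pra)
# and plasma aldosterone concentration (pac) for the nephrotic cohort.
# Units: posm, uosm mOsm/L; u_na, u_k, u_cl, urinary_ag mEq/L;
# pra ng/mL/h; pac pg/mL.
# Row 1 renin/aldosterone is ambiguous in the source table (the printed run
# "19.0618.0" reads as either 19.0/618.0 or 19.06/18.0); this fixture adopts
# pra 19.0, pac 18.0.
patient_id,posm,uosm,u_na,u_k,u_cl,urinary_ag,pra,pac
1,276,810,20,54.8,46,28.8,19.0,18.0
2,283,722,80,52.0,96,36.0,0.6,10.0
3,284,499,152,19.0,141,30.0,1.1,39.1
4,287,528,117,34.6,90,61.6,0.1,10.0
5,282,592,127,46.2,141,32.2,0.2,40.1
6,281,290,53,22.0,49,26.0,13.0,191.0
7,293,602,155,28.4,133,50.4,0.4,70.1
8,290,818,42,68.4,108,2.4,16.0,309.0
9,298,749,81,39.2,81,39.2,18.0,77.4
10,285,417,39,20.1,31,28.1,1.5,67.8
11,306,432,113,17.0,101,29.0,0.8,101.0
12,285,244,114,100.0,159,55.0,0.6,10.0
13,294,813,36,61.9,39,58.9,2.6,45.0
14,286,466,105,32.3,87,50.3,0.7,27.9
15,294,475,85,31.1,72,44.1,1.6,50.4
16,282,328,138,26.9,126,38.9,0.5,19.2
17,293,560,56,30.1,21,65.1,0.4,10.0
18,286,484,37,51.5,22,66.5,0.9,33.6
19,301,392,111,32.3,86,57.3,0.8,10.0
20,332,796,18,72.3,12,78.3,0.7,16.4
21,281,453,26,42.9,25,43.9,0.5,32.1
22,287,474,62,24.5,46,40.5,13.0,85.6
23,291,296,109,14.7,110,13.7,0.4,10.0
24,267,264,33,27.4,31,29.4,0.4,26.7
25,297,275,33,16.6,16,33.6,2.9,20.6
26,285,248,48,20.2,40,28.2,0.2,53.1
27,310,431,35,57.1,25,67.1,1.2,50.8
28,302,274,41,19.1,24,36.1,0.3,59.1
29,286,196,60,15.8,61,14.8,0.1,72.4
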