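# Physicochemical (Stewart) panel for the nephrotic cohort, as reported:
# a_tot, sida are inputs to the pipeline; delta_a_tot, delta_sida, side, sig,
# sig_minus_lactate and the two verdict columns are the reported derived
# values the package must reproduce.
# Units: paco2 Torr; a_tot, delta_a_tot, sida, delta_sida, side, sig,
# sig_minus_lactate mEq/L; lactate mmol/L. agplus: 1 = flagged increased-AG
# acidosis (SIG > 7.0), 0 = not flagged. Reference (control) means:
# a_tot 14.09, sida 42.7, sig 4.2, lactate 0.9.
patient_id,ph,paco2,a_tot,delta_a_tot,sida,delta_sida,verdict,side,sig,agplus,lactate,sig_minus_lactate
1,7.43,34.00,6.16,7.93,34.8,7.9,Neutral,28.1,6.7,0,1.3,5.4
2,7.48,25.70,7.69,6.40,34.1,8.6,Acidosis,26.4,7.7,1,0.6,7.0
3,7.46,34.10,7.69,6.40,35.8,6.9,Acidosis,31.2,4.6,0,1.2,3.5
4,7.44,38.70,7.13,6.96,36.5,6.2,Alkalosis,32.8,3.7,0,2.1,1.6
5,7.45,36.40,7.47,6.62,34.4,8.3,Acidosis,31.9,2.5,0,1.0,1.5
6,7.45,35.00,9.49,4.60,35.2,7.5,Acidosis,33.2,2.0,0,1.6,0.4
7,7.43,37.40,8.60,5.49,37.1,5.6,Acidosis,32.8,4.3,0,0.9,3.5
8,7.44,35.10,5.02,9.07,35.1,7.6,Alkalosis,28.2,6.9,0,3.3,3.6
9,7.55,27.90,4.91,9.18,38.0,4.7,Alkalosis,28.7,9.3,1,2.4,6.8
10,7.43,43.20,5.02,9.07,40.6,2.1,Alkalosis,33.0,7.6,1,1.8,5.8
11,7.34,34.90,8.93,5.16,37.3,5.4,Acidosis,27.1,10.2,1,4.2,6.0
12,7.43,41.30,6.67,7.42,37.9,4.8,Alkalosis,33.1,4.8,0,0.9,3.9
13,7.42,40.80,5.25,8.84,35.3,7.4,Alkalosis,30.9,4.4,0,1.5,2.9
14,7.56,29.40,8.91,5.18,39.7,3.0,Alkalosis,34.7,5.0,0,1.3,3.7
15,7.42,42.10,10.44,3.65,40.3,2.4,Alkalosis,37.0,3.3,0,1.0,2.3
16,7.36,40.00,7.83,6.26,36.5,6.2,Neutral,29.9,6.6,0,2.6,4.0
17,7.47,33.10,3.89,10.20,34.5,8.2,Alkalosis,27.2,7.3,1,1.4,6.0
18,7.45,36.90,6.84,7.25,36.4,6.3,Alkalosis,31.5,4.9,0,0.9,4.0
19,7.43,43.90,7.04,7.05,39.5,3.2,Alkalosis,35.4,4.1,0,3.8,0.4
20,7.42,41.30,7.05,7.04,41.1,1.6,Alkalosis,32.9,8.2,1,1.5,6.7
21,7.49,28.40,4.24,9.85,31.7,11.0,Acidosis,25.3,6.4,0,1.2,5.2
22,7.42,32.00,7.77,6.32,38.9,3.8,Alkalosis,28.1,10.8,1,1.7,9.1
23,7.43,44.60,6.00,8.09,38.5,4.2,Alkalosis,35.0,3.5,0,1.0,2.5
24,7.45,30.80,5.20,8.89,30.7,12.0,Acidosis,25.8,4.9,0,1.2,3.6
25,7.45,31.90,7.27,6.82,36.5,6.2,Alkalosis,29.0,7.5,1,1.2,6.4
26,7.48,26.50,6.69,7.40,36.0,6.7,Alkalosis,25.9,10.1,1,1.0,9.1
27,7.29,31.50,8.89,5.20,35.0,7.7,Acidosis,23.6,11.4,1,0.9,10.4
28,7.32,28.70,8.53,5.56,36.4,6.3,Acidosis,22.8,13.6,1,1.9,11.7
29,7.40,21.50,7.64,6.45,33.9,8.8,Acidosis,20.6,13.3,1,1.9,11.4
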