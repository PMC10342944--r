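donor_id,age,gender,bmi,disease_years,rf,acpa,prednisolone_mg,das28_t0,das28_t1,das28_t2,das28_t3,sdai_t0,sdai_t1,sdai_t2,sdai_t3
RA_01,49,f,32.4,6.9,59.3,184,0,4.06,4.08,4.10,3.17,11.3,11.8,9.6,7.3
RA_03,54,f,27.2,0.3,14,0.9,0,4.46,4.02,3.18,2.50,15.1,12.9,10.0,7.5
RA_09,22,f,17.2,21.2,14,0.5,0,5.54,4.63,4.49,3.98,41.4,41.4,41.1,36.3
RA_13,61,f,24.0,11.3,49.9,300,0,4.97,5.76,5.68,6.64,24.3,33.5,27.3,46.0
RA_08,65,f,20.0,5.1,935.4,272,2,4.42,3.92,3.63,3.24,30.8,21.7,22.9,19.4
RA_16,41,f,25.4,0.9,14,0.4,2.5,2.32,2.18,2.47,2.18,6.3,4.6,5.7,4.9
RA_12,31,f,22.7,7.3,70.6,212,5,3.13,2.75,1.99,2.48,13.0,7.4,6.0,6.3
RA_18,65,f,20.5,4.6,14,340,5,4.98,4.47,3.98,3.17,26.3,22.2,18.1,14.8
RA_19,70,f,25.1,6.6,14,0.4,5,5.96,5.37,4.64,4.37,33.5,23.5,21.3,19.7
RA_05,77,m,20.6,36.1,31.3,67,0,5.04,3.23,2.66,2.58,19.5,8.8,12.2,5.6
RA_04,50,f,21.5,1.7,31.3,340,5,1.82,1.25,1.05,0.49,3.6,2.8,2.7,0.1
RA_17,52,f,20.8,8.6,104,285,5,4.78,4.70,3.21,3.75,24.7,23.6,18.1,17.6
RA_11,72,f,27.8,16.1,195.1,275,6,5.20,5.03,4.45,3.96,28.4,20.8,14.0,10.5
RA_02,63,f,32.9,14.9,14,0.4,10,7.05,6.26,6.70,6.18,49.9,36.8,44.9,41.2
RA_10,53,f,25.5,35.2,600,12.4,0,2.64,1.93,1.41,1.55,11.1,7.6,3.2,2.6
RA_07,52,f,39.9,0.9,151,60,5,5.83,4.57,4.31,2.93,38.3,24.4,21.2,7.1
RA_14,34,f,23.9,20.3,119.7,30,15,3.97,5.16,3.89,3.61,19.3,27.6,19.4,16.3
RA_20,61,f,26.1,25.6,14,0.8,5,4.93,5.06,4.26,3.49,24.7,25.1,15.4,14.5
RA_06,22,f,25.5,6.1,240.4,2.6,7.5,3.24,2.62,1.93,1.96,11.4,6.0,5.5,1.7
RA_15,30,f,22.3,1.9,14,136,10,3.45,3.17,2.51,2.23,13.6,11.1,6.1,6.0
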