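metal_id,cmc,AN,AW,AR,CR,r,MP,D,Eh,BP,dIP,dE0,Xm,logKOH_abs,Xm2r,Z2_r,AN_dIP,sigma_p,IP,AR_AW,Z,Z_r2,Z_AR2,Z_r,Z_AR,x,Z_rx
Cd,2,48,112.4,1.71,1.48,0.97,321,8.65,99.57,321,7.91,0.40,1.69,10.1,2.71,4.21,6.07,0.08,16.90,0.02,2,2.22,0.68,2.11,1.17,1.70,1.24
Cr(III),570,24,51.99,1.85,1.18,0.52,1857,7.19,344.3,2672,14.5,0.41,1.66,4.00,1.71,14.5,1.66,0.11,30.96,0.04,3,7.80,0.88,4.84,1.62,1.60,3.02
Cr(VI),16,24,51.99,1.85,1.18,0.52,1857,7.19,344.3,2672,21.2,0.13,1.66,4.00,1.21,81.8,1.13,0.11,90.63,0.04,6,31.0,1.75,13.6,3.24,1.60,8.52
Cu,13,29,63.55,1.57,1.17,0.73,1085,8.96,300.3,2567,12.6,0.16,1.90,8.00,2.64,5.48,2.31,0.10,20.30,0.02,2,3.75,0.81,2.74,1.27,1.90,1.44
Hg,1.4,80,200.6,1.76,1.49,1.02,-39,13.6,59.23,357,8.32,0.91,2.00,3.40,4.08,3.92,9.62,0.07,42.32,0.01,2,1.92,0.65,1.96,1.14,1.90,1.03
Ni,470,28,58.69,1.62,1.15,0.69,1453,8.90,370.4,2732,10.5,0.23,1.91,9.90,2.52,5.80,2.66,0.13,18.76,0.03,2,4.20,0.76,2.90,1.23,1.80,1.61
Ag,3.2,47,107.9,1.75,1.34,1.26,961,10.5,250.6,2163,7.57,0.80,1.93,12.4,4.28,0.87,6.21,0.07,18.17,0.02,1,0.76,0.33,0.87,0.57,1.90,0.46
Zn,120,30,65.39,1.53,1.25,0.74,420,7.13,115.3,907,8.57,0.76,1.65,8.20,2.01,5.41,3.50,0.12,17.96,0.02,2,3.65,0.85,2.70,1.31,1.60,1.69
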