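group,block,period,metal_id,predicted_cmc,lc50_nominal,lc50_measured
IIIB,IIIB,4,Sc,11,100,29
IIIB,IIIB,5,Y,2.20,183,66
VB,VB,4,V,89,989,1251
VB,VB,5,Nb,27,250,26
VB,VB,6,Ta,32,353,2
VIII,VIIIa,4,Co,61,16,16
VIII,VIIIa,5,Rh,32,980,804
VIII,VIIIb,4,Ni,75,77,75
VIII,VIIIb,6,Pt,42,131,110
IB,IB,4,Cu,39,56,36
IB,IB,5,Ag,1.64,1.72,0.25
IB,IB,6,Au,0.92,841,446
IIB,IIB,4,Zn,35,70,56
IIB,IIB,5,Cd,3.47,0.57,0.15
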