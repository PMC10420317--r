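group,variable,median,q25,q75
NW,age,29.15,26.46,33.14
NW,bmi,22.85,20.79,24.70
NW,wc,78.0,76.3,82.8
NW,sbp,120,110,120
NW,dbp,70,70,75
NW,glucose,87,82.25,94.25
NW,insulin,6.65,5.13,8.80
NW,homa_ir,1.54,1.07,1.84
NW,tc,173,158,200.50
NW,hdl,65,56.25,70.75
NW,ldl,106.50,86.25,120.50
NW,tg,63,53,85.75
NW,crp,0.10,0.03,0.20
NW,cer16,0.4463,0.3834,0.5280
NW,cer18,0.0663,0.0557,0.0790
NW,cer241,0.7663,0.5601,0.9362
NW,cer240,3.7086,2.9225,4.0040
NW,frs,1.000,0.675,1.350
NW,va,16.000,13.750,18.000
OB_METS_NEG,age,27.38,21.35,35.65
OB_METS_NEG,bmi,42.88,40.75,119.25
OB_METS_NEG,wc,110.0,106.0,119.3
OB_METS_NEG,sbp,120,120,130
OB_METS_NEG,dbp,80,77.50,80
OB_METS_NEG,glucose,83,80,88.25
OB_METS_NEG,insulin,15.85,11,23.55
OB_METS_NEG,homa_ir,3.23,2.23,4.68
OB_METS_NEG,tc,160.50,133.25,188.50
OB_METS_NEG,hdl,45.50,39.50,50.25
OB_METS_NEG,ldl,101.50,77.75,122.25
OB_METS_NEG,tg,96,85.75,123.25
OB_METS_NEG,crp,0.50,0.28,1.03
OB_METS_NEG,cer16,0.4359,0.4025,0.4727
OB_METS_NEG,cer18,0.1121,0.0794,0.1377
OB_METS_NEG,cer241,0.9581,0.8408,1.1890
OB_METS_NEG,cer240,2.1955,1.7563,3.1066
OB_METS_NEG,frs,1.150,0.600,1.675
OB_METS_NEG,va,16.000,13.250,19.750
OB_METS_POS,age,30.43,23.98,41.18
OB_METS_POS,bmi,43.44,41.53,46.54
OB_METS_POS,wc,120.0,113.3,126.5
OB_METS_POS,sbp,130,130,140
OB_METS_POS,dbp,80,80,90
OB_METS_POS,glucose,86,82.25,94.75
OB_METS_POS,insulin,25.05,19.08,30.25
OB_METS_POS,homa_ir,5.30,4.32,6.21
OB_METS_POS,tc,163,148,196
OB_METS_POS,hdl,37.50,32.50,43.75
OB_METS_POS,ldl,107.50,96,124.75
OB_METS_POS,tg,125.50,103.50,159.25
OB_METS_POS,crp,0.55,0.40,1.08
OB_METS_POS,cer16,0.4533,0.3815,0.5484
OB_METS_POS,cer18,0.1242,0.1053,0.1714
OB_METS_POS,cer241,1.1021,0.8999,1.3634
OB_METS_POS,cer240,2.3265,1.9734,3.0387
OB_METS_POS,frs,2.450,1.100,4.325
OB_METS_POS,va,23.500,17.750,30.000
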