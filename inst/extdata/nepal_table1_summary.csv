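stratum,element,n,gm_ug_per_kg,sd_ug_per_kg,min_ug_per_kg,max_ug_per_kg
Province 1,Cd,49,15.4,21.9,1.76,95.4
Province 1,As,49,36.6,18.8,6.43,92.3
Province 1,Pb,49,15.7,17.3,5.49,121.4
Province 1,Cu,49,1078,1920,264,10059
Madhesh,Cd,20,17.5,13.5,6.80,46.4
Madhesh,As,20,47.9,28.5,17.0,121
Madhesh,Pb,20,17.3,10.3,5.72,36.9
Madhesh,Cu,20,1364,1601,453,6559
Bagmati,Cd,27,14.9,11.5,2.68,55.9
Bagmati,As,27,46.4,14.8,25.3,81.7
Bagmati,Pb,27,13.5,9.21,5.91,43.0
Bagmati,Cu,27,1000,251,519,1556
Gandaki,Cd,13,9.93,6.71,1.31,23.5
Gandaki,As,13,47.2,15.8,32.1,85.6
Gandaki,Pb,13,19.7,25.5,7.94,87.4
Gandaki,Cu,13,1100,398,491,1959
Lumbini,Cd,35,17.2,14.8,1.73,68.6
Lumbini,As,35,49.2,18.1,23.1,85.8
Lumbini,Pb,35,18.4,10.2,6.02,51.3
Lumbini,Cu,35,949,358,271,2016
Karnali,Cd,10,15.7,12.5,3.86,45.4
Karnali,As,10,54.4,20.3,23.5,83.3
Karnali,Pb,10,15.6,8.97,6.94,35.1
Karnali,Cu,10,1072,194,823,1383
Sudurpashchim,Cd,16,17.0,12.5,4.26,51.9
Sudurpashchim,As,16,35.1,13.9,17.3,60.2
Sudurpashchim,Pb,16,12.9,5.94,7.98,26.8
Sudurpashchim,Cu,16,1051,316,550,1624
Total Nepal,Cd,170,15.5,16.0,1.31,95.4
Total Nepal,As,170,43.4,19.6,6.43,121
Total Nepal,Pb,170,16.0,14.0,5.49,121.4
Total Nepal,Cu,170,1066,1210,264,10059
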