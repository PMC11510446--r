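drug,cell_system,albumin_species,albumin_pct,format,ec50_pm,sd_pm
Dulaglutide,CHO,none,0,CHO 0% SA,39.4,15.3
Dulaglutide,CHO,BSA,0.1,CHO 0.1% BSA,16,11.7
Dulaglutide,CHO,OA,0.1,CHO 0.1% OA,31.8,9.1
Dulaglutide,CHO,HSA,4.4,CHO 4.4% HSA,50.6,13
Dulaglutide,EndoC,BSA,0.1,EndoC 0.1% BSA,2440,2100
Semaglutide,CHO,none,0,CHO 0% SA,0.915,0.36
Semaglutide,CHO,BSA,0.1,CHO 0.1% BSA,31,22.4
Semaglutide,CHO,OA,0.1,CHO 0.1% OA,3.45,1.6
Semaglutide,CHO,HSA,4.4,CHO 4.4% HSA,3400,2200
Semaglutide,EndoC,BSA,0.1,EndoC 0.1% BSA,7380,3200
Liraglutide,CHO,none,0,CHO 0% SA,1.2,0.55
Liraglutide,CHO,BSA,0.1,CHO 0.1% BSA,1.56,2.22
Liraglutide,CHO,OA,0.1,CHO 0.1% OA,14.3,5.9
Liraglutide,CHO,HSA,4.4,CHO 4.4% HSA,475,329
Liraglutide,EndoC,BSA,0.1,EndoC 0.1% BSA,257,150
Exenatide,CHO,none,0,CHO 0% SA,2.14,0.64
Exenatide,CHO,BSA,0.1,CHO 0.1% BSA,2.32,0.68
Exenatide,CHO,OA,0.1,CHO 0.1% OA,1.99,1
Exenatide,CHO,HSA,4.4,CHO 4.4% HSA,3.15,1.83
Exenatide,EndoC,BSA,0.1,EndoC 0.1% BSA,366,180
Lixisenatide,CHO,none,0,CHO 0% SA,1.31,0.04
Lixisenatide,CHO,BSA,0.1,CHO 0.1% BSA,3.16,0.39
Lixisenatide,CHO,OA,0.1,CHO 0.1% OA,3.1,2.54
Lixisenatide,CHO,HSA,4.4,CHO 4.4% HSA,5.79,0.74
Lixisenatide,EndoC,BSA,0.1,EndoC 0.1% BSA,100,NA
GLP-1(7-36)NH2,CHO,none,0,CHO 0% SA,1.77,0.55
GLP-1(7-36)NH2,CHO,BSA,0.1,CHO 0.1% BSA,3.09,1
GLP-1(7-36)NH2,CHO,OA,0.1,CHO 0.1% OA,5.32,1.48
GLP-1(7-36)NH2,CHO,HSA,4.4,CHO 4.4% HSA,4.53,2.71
GLP-1(7-36)NH2,EndoC,BSA,0.1,EndoC 0.1% BSA,136,110
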