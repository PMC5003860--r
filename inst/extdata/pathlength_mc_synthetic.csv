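wavelength_nm,X_mm
450,0.8139
460,1.027
470,1.2708
480,1.4998
490,1.6595
500,1.801
510,1.7472
520,1.487
530,1.2532
540,1.0803
550,1.0701
560,1.298
570,1.2419
580,1.1292
590,2.1611
600,3.99
610,5.5984
620,6.9109
630,8.2641
640,9.4588
650,10.1511
660,11.0262
670,11.727
680,12.4799
690,13.1874
700,13.6667
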