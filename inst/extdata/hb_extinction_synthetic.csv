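wavelength_nm,xi_hbo,xi_hbr
450,62816,103292
451,61004.4,100162.8
452,59192.8,97033.6
453,57381.2,93904.4
454,55569.6,90775.2
455,53758,87646
456,51946.4,84516.8
457,50134.8,81387.6
458,48323.2,78258.4
459,46511.6,75129.2
460,44700,72000
461,43550.9,69600
462,42401.8,67200
463,41252.7,64800
464,40103.6,62400
465,38954.5,60000
466,37805.4,57600
467,36656.3,55200
468,35507.2,52800
469,34358.1,50400
470,33209,48000
471,32551,46200
472,31893,44400
473,31235,42600
474,30577,40800
475,29919,39000
476,29261,37200
477,28603,35400
478,27945,33600
479,27287,31800
480,26629,30000
481,26304.9,29300
482,25980.8,28600
483,25656.7,27900
484,25332.6,27200
485,25008.5,26500
486,24684.4,25800
487,24360.3,25100
488,24036.2,24400
489,23712.1,23700
490,23388,23000
491,23052.7,22786.2
492,22717.4,22572.4
493,22382.1,22358.6
494,22046.8,22144.8
495,21711.5,21931
496,21376.2,21717.2
497,21040.9,21503.4
498,20705.6,21289.6
499,20370.3,21075.8
500,20035,20862
501,20231.5,21175.8
502,20428,21489.6
503,20624.5,21803.4
504,20821,22117.2
505,21017.5,22431
506,21214,22744.8
507,21410.5,23058.6
508,21607,23372.4
509,21803.5,23686.2
510,22000,24000
511,22600,24700
512,23200,25400
513,23800,26100
514,24400,26800
515,25000,27500
516,25600,28200
517,26200,28900
518,26800,29600
519,27400,30300
520,28000,31000
521,28920,31800
522,29840,32600
523,30760,33400
524,31680,34200
525,32600,35000
526,34071.4,35807.2
527,35542.8,36614.4
528,37014.2,37421.6
529,38485.6,38228.8
530,39957,39036
531,41165.6,39728.8
532,42374.2,40421.6
533,43582.8,41114.4
534,44791.4,41807.2
535,46000,42500
536,47447.2,43318.4
537,48894.4,44136.8
538,50341.6,44955.2
539,51788.8,45773.6
540,53236,46592
541,53588.8,47373.6
542,53941.6,48155.2
543,54294.4,48936.8
544,54647.2,49718.4
545,55000,50500
546,54000,50800
547,53000,51100
548,52000,51400
549,51000,51700
550,50000,52000
551,48800,52282.4
552,47600,52564.8
553,46400,52847.2
554,45200,53129.6
555,44000,53412
556,41722.6,53487.2
557,39445.2,53562.4
558,37167.8,53637.6
559,34890.4,53712.8
560,32613,53788
561,32890.4,53030.4
562,33167.8,52272.8
563,33445.2,51515.2
564,33722.6,50757.6
565,34000,50000
566,35200,49000
567,36400,48000
568,37600,47000
569,38800,46000
570,40000,45000
571,44000,44200
572,48000,43400
573,52000,42600
574,56000,41800
575,60000,41000
576,61000,40600
577,62000,40200
578,58034.7,39140
579,54069.3,38080
580,50104,37020
581,45683.2,36216
582,41262.4,35412
583,36841.6,34608
584,32420.8,33804
585,28000,33000
586,25280,31720
587,22560,30440
588,19840,29160
589,17120,27880
590,14400,26600
591,12960,25480
592,11520,24360
593,10080,23240
594,8640,22120
595,7200,21000
596,6400,19735.4
597,5600,18470.8
598,4800,17206.2
599,4000,15941.6
600,3200,14677
601,2920,14101.6
602,2640,13526.2
603,2360,12950.8
604,2080,12375.4
605,1800,11800
606,1741.2,11328.6
607,1682.4,10857.2
608,1623.6,10385.8
609,1564.8,9914.4
610,1506,9443
611,1449.6,9149.7
612,1393.2,8856.4
613,1336.8,8563.1
614,1280.4,8269.8
615,1224,7976.5
616,1167.6,7683.2
617,1111.2,7389.9
618,1054.8,7096.6
619,998.4,6803.3
620,942,6510
621,908.8,6373.9
622,875.6,6237.8
623,842.4,6101.7
624,809.2,5965.6
625,776,5829.5
626,742.8,5693.4
627,709.6,5557.3
628,676.4,5421.2
629,643.2,5285.1
630,610,5149
631,593.2,5068.6
632,576.4,4988.2
633,559.6,4907.8
634,542.8,4827.4
635,526,4747
636,509.2,4666.6
637,492.4,4586.2
638,475.6,4505.8
639,458.8,4425.4
640,442,4345
641,434.6,4285.5
642,427.2,4226
643,419.8,4166.5
644,412.4,4107
645,405,4047.5
646,397.6,3988
647,390.2,3928.5
648,382.8,3869
649,375.4,3809.5
650,368,3750
651,363.2,3697.7
652,358.4,3645.4
653,353.6,3593.1
654,348.8,3540.8
655,344,3488.5
656,339.2,3436.2
657,334.4,3383.9
658,329.6,3331.6
659,324.8,3279.3
660,320,3227
661,317.4,3183.9
662,314.8,3140.8
663,312.2,3097.7
664,309.6,3054.6
665,307,3011.5
666,304.4,2968.4
667,301.8,2925.3
668,299.2,2882.2
669,296.6,2839.1
670,294,2796
671,292.4,2757.2
672,290.8,2718.4
673,289.2,2679.6
674,287.6,2640.8
675,286,2602
676,284.4,2563.2
677,282.8,2524.4
678,281.2,2485.6
679,279.6,2446.8
680,278,2408
681,277.8,2372.3
682,277.6,2336.6
683,277.4,2300.9
684,277.2,2265.2
685,277,2229.5
686,276.8,2193.8
687,276.6,2158.1
688,276.4,2122.4
689,276.2,2086.7
690,276,2051
691,277.4,2025.3
692,278.8,1999.6
693,280.2,1973.9
694,281.6,1948.2
695,283,1922.5
696,284.4,1896.8
697,285.8,1871.1
698,287.2,1845.4
699,288.6,1819.7
700,290,1794
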