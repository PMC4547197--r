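wavelength_nm,value
300,0
302,0
304,0
306,0
308,0
310,0
312,0
314,0
316,0
318,0
320,0
322,0
324,0
326,0
328,1e-06
330,1e-06
332,1e-06
334,2e-06
336,2e-06
338,3e-06
340,5e-06
342,6e-06
344,9e-06
346,1.2e-05
348,1.5e-05
350,2.1e-05
352,2.8e-05
354,3.7e-05
356,4.8e-05
358,6.4e-05
360,8.3e-05
362,0.000108
364,0.00014
366,0.000181
368,0.000233
370,0.000298
372,0.00038
374,0.000482
376,0.000609
378,0.000766
380,0.000958
382,0.001194
384,0.001481
386,0.00183
388,0.00225
390,0.002754
392,0.003356
394,0.004072
396,0.004918
398,0.005915
400,0.007081
402,0.00844
404,0.010015
406,0.011831
408,0.013915
410,0.016293
412,0.018994
414,0.022043
416,0.025468
418,0.029296
420,0.033549
422,0.038249
424,0.043414
426,0.049058
428,0.05519
430,0.061814
432,0.068926
434,0.076515
436,0.084564
438,0.093046
440,0.101925
442,0.111158
444,0.120691
446,0.130464
448,0.140406
450,0.150441
452,0.160485
454,0.170451
456,0.180246
458,0.189777
460,0.198951
462,0.207678
464,0.215871
466,0.223452
468,0.230352
470,0.236516
472,0.241902
474,0.246487
476,0.250269
478,0.253265
480,0.25552
482,0.257102
484,0.258106
486,0.258657
488,0.258905
490,0.259028
492,0.259232
494,0.259745
496,0.260817
498,0.262716
500,0.265722
502,0.270124
504,0.27621
506,0.284264
508,0.294554
510,0.307327
512,0.322795
514,0.34113
516,0.362453
518,0.386828
520,0.414247
522,0.444631
524,0.477821
526,0.513575
528,0.551567
530,0.591389
532,0.632557
534,0.674512
536,0.716638
538,0.758269
540,0.798704
542,0.837229
544,0.873128
546,0.905709
548,0.934319
550,0.958363
552,0.977326
554,0.99078
556,0.998407
558,1
560,0.995473
562,0.984864
564,0.968329
566,0.946142
568,0.918681
570,0.88642
572,0.849909
574,0.809763
576,0.766637
578,0.721214
580,0.674183
582,0.626221
584,0.577977
586,0.53006
588,0.483024
590,0.437362
592,0.393497
594,0.351776
596,0.312476
598,0.275799
600,0.241876
602,0.210773
604,0.182499
606,0.157011
608,0.134221
610,0.114007
612,0.09622
614,0.080691
616,0.067236
618,0.055667
620,0.045795
622,0.037434
624,0.030404
626,0.024536
628,0.019675
630,0.015676
632,0.01241
634,0.009762
636,0.00763
638,0.005926
640,0.004573
642,0.003506
644,0.002671
646,0.002022
648,0.001521
650,0.001137
652,0.000844
654,0.000623
656,0.000457
658,0.000333
660,0.000241
662,0.000173
664,0.000124
666,8.8e-05
668,6.2e-05
670,4.3e-05
672,3e-05
674,2.1e-05
676,1.4e-05
678,1e-05
680,7e-06
682,5e-06
684,3e-06
686,2e-06
688,1e-06
690,1e-06
692,1e-06
694,0
696,0
698,0
700,0
702,0
704,0
706,0
708,0
710,0
712,0
714,0
716,0
718,0
720,0
722,0
724,0
726,0
728,0
730,0
732,0
734,0
736,0
738,0
740,0
742,0
744,0
746,0
748,0
750,0
752,0
754,0
756,0
758,0
760,0
762,0
764,0
766,0
768,0
770,0
772,0
774,0
776,0
778,0
780,0
782,0
784,0
786,0
788,0
790,0
792,0
794,0
796,0
798,0
800,0
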