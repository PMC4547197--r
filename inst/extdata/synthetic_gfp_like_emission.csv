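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
328,0
330,0
332,0
334,0
336,0
338,0
340,0
342,0
344,0
346,0
348,0
350,0
352,0
354,0
356,0
358,0
360,0
362,0
364,0
366,0
368,0
370,0
372,0
374,0
376,0
378,0
380,0
382,0
384,0
386,0
388,1e-06
390,1e-06
392,1e-06
394,2e-06
396,2e-06
398,3e-06
400,4e-06
402,6e-06
404,7e-06
406,1e-05
408,1.4e-05
410,1.8e-05
412,2.4e-05
414,3.2e-05
416,4.2e-05
418,5.6e-05
420,7.3e-05
422,9.5e-05
424,0.000123
426,0.000159
428,0.000205
430,0.000263
432,0.000335
434,0.000426
436,0.000541
438,0.000684
440,0.000863
442,0.001088
444,0.001373
446,0.001734
448,0.002197
450,0.002796
452,0.003581
454,0.00462
456,0.006008
458,0.007877
460,0.010404
462,0.013827
464,0.018452
466,0.024672
468,0.032968
470,0.043918
472,0.05819
474,0.076525
476,0.099709
478,0.128521
480,0.163674
482,0.205733
484,0.25503
486,0.31157
488,0.374948
490,0.444287
492,0.518205
494,0.594819
496,0.671808
498,0.746517
500,0.816111
502,0.877764
504,0.928863
506,0.967215
508,0.991218
510,1
512,0.993485
514,0.972398
516,0.93819
518,0.892914
520,0.839048
522,0.779289
524,0.716355
526,0.652794
528,0.590833
530,0.532273
532,0.478431
534,0.430134
536,0.387751
538,0.351258
540,0.320319
542,0.294382
544,0.272762
546,0.25472
548,0.239526
550,0.226507
552,0.215071
554,0.204728
556,0.195089
558,0.185864
560,0.176849
562,0.167914
564,0.158986
566,0.150041
568,0.141084
570,0.132145
572,0.123268
574,0.114506
576,0.10591
578,0.097535
580,0.08943
582,0.081637
584,0.074195
586,0.067133
588,0.060475
590,0.054235
592,0.048424
594,0.043044
596,0.038091
598,0.03356
600,0.029436
602,0.025704
604,0.022346
606,0.019341
608,0.016665
610,0.014296
612,0.012209
614,0.010381
616,0.008787
618,0.007405
620,0.006213
622,0.00519
624,0.004315
626,0.003573
628,0.002945
630,0.002416
632,0.001974
634,0.001605
636,0.0013
638,0.001048
640,0.000841
642,0.000672
644,0.000534
646,0.000423
648,0.000334
650,0.000262
652,0.000205
654,0.000159
656,0.000123
658,9.5e-05
660,7.3e-05
662,5.6e-05
664,4.2e-05
666,3.2e-05
668,2.4e-05
670,1.8e-05
672,1.4e-05
674,1e-05
676,7e-06
678,6e-06
680,4e-06
682,3e-06
684,2e-06
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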