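wavelength_nm,value
300,0.004625
302,0.005699
304,0.006992
306,0.00854
308,0.010385
310,0.012572
312,0.015152
314,0.018181
316,0.021718
318,0.025828
320,0.030581
322,0.036046
324,0.042301
326,0.04942
328,0.057482
330,0.066563
332,0.076736
334,0.088071
336,0.100633
338,0.114476
340,0.129646
342,0.146176
344,0.164082
346,0.183364
348,0.204005
350,0.225961
352,0.249172
354,0.273548
356,0.298976
358,0.32532
360,0.352415
362,0.380074
364,0.408085
366,0.436218
368,0.464223
370,0.491835
372,0.518779
374,0.544772
376,0.569531
378,0.592775
380,0.614233
382,0.633646
384,0.650775
386,0.665406
388,0.677351
390,0.686459
392,0.692612
394,0.695732
396,0.695782
398,0.69277
400,0.686744
402,0.677797
404,0.666063
406,0.651718
408,0.634974
410,0.61608
412,0.595319
414,0.573002
416,0.549466
418,0.525075
420,0.500209
422,0.475268
424,0.450667
426,0.426831
428,0.404193
430,0.383194
432,0.364273
434,0.34787
436,0.334412
438,0.324315
440,0.317969
442,0.315735
444,0.317928
446,0.324812
448,0.336579
450,0.353346
452,0.375131
454,0.401848
456,0.433293
458,0.469138
460,0.508922
462,0.552054
464,0.597817
466,0.645375
468,0.693791
470,0.742047
472,0.789072
474,0.833767
476,0.875045
478,0.911863
480,0.94326
482,0.968387
484,0.986541
486,0.997193
488,1
490,0.994825
492,0.981737
494,0.961007
496,0.933094
498,0.898629
500,0.858387
502,0.813252
504,0.76419
506,0.712208
508,0.658322
510,0.603522
512,0.548743
514,0.494838
516,0.442563
518,0.392558
520,0.34534
522,0.301304
524,0.260722
526,0.22375
528,0.190441
530,0.160758
532,0.134585
534,0.111746
536,0.092019
538,0.075151
540,0.06087
542,0.048898
544,0.038957
546,0.030781
548,0.024121
550,0.018747
552,0.01445
554,0.011046
556,0.008375
558,0.006297
560,0.004696
562,0.003473
564,0.002548
566,0.001853
568,0.001337
570,0.000957
572,0.000679
574,0.000478
576,0.000334
578,0.000231
580,0.000159
582,0.000108
584,7.3e-05
586,4.9e-05
588,3.2e-05
590,2.1e-05
592,1.4e-05
594,9e-06
596,6e-06
598,4e-06
600,2e-06
602,1e-06
604,1e-06
606,1e-06
608,0
610,0
612,0
614,0
616,0
618,0
620,0
622,0
624,0
626,0
628,0
630,0
632,0
634,0
636,0
638,0
640,0
642,0
644,0
646,0
648,0
650,0
652,0
654,0
656,0
658,0
660,0
662,0
664,0
666,0
668,0
670,0
672,0
674,0
676,0
678,0
680,0
682,0
684,0
686,0
688,0
690,0
692,0
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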