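wavelength_nm,value
300,0.000115
302,0.000158
304,0.000216
306,0.000292
308,0.000394
310,0.000527
312,7e-04
314,0.000925
316,0.001214
318,0.001583
320,0.002052
322,0.002642
324,0.00338
326,0.004297
328,0.005428
330,0.006813
332,0.008496
334,0.010528
336,0.012964
338,0.015861
340,0.019282
342,0.023294
344,0.027961
346,0.033352
348,0.039533
350,0.046565
352,0.054506
354,0.063406
356,0.073306
358,0.084235
360,0.096212
362,0.109239
364,0.123308
366,0.138394
368,0.154464
370,0.171472
372,0.189368
374,0.2081
376,0.227617
378,0.247878
380,0.268858
382,0.29055
384,0.31297
386,0.336165
388,0.360208
390,0.385199
392,0.411262
394,0.438534
396,0.467155
398,0.497252
400,0.528925
402,0.562224
404,0.597129
406,0.633532
408,0.67122
410,0.709863
412,0.749001
414,0.788051
416,0.82631
418,0.862972
420,0.897155
422,0.927928
424,0.954355
426,0.975533
428,0.990641
430,0.998976
432,1
434,0.993364
436,0.978937
438,0.956815
440,0.927322
442,0.891
444,0.848584
446,0.800972
448,0.749185
450,0.694323
452,0.637516
454,0.579886
456,0.522497
458,0.466323
460,0.412219
462,0.360899
464,0.312927
466,0.268711
468,0.228505
470,0.192427
472,0.160466
474,0.132507
476,0.10835
478,0.087729
480,0.070336
482,0.055837
484,0.043892
486,0.034162
488,0.026328
490,0.02009
492,0.015179
494,0.011356
496,0.008412
498,0.00617
500,0.00448
502,0.003222
504,0.002294
506,0.001617
508,0.001129
510,0.00078
512,0.000534
514,0.000362
516,0.000243
518,0.000161
520,0.000106
522,6.9e-05
524,4.5e-05
526,2.8e-05
528,1.8e-05
530,1.1e-05
532,7e-06
534,4e-06
536,3e-06
538,2e-06
540,1e-06
542,1e-06
544,0
546,0
548,0
550,0
552,0
554,0
556,0
558,0
560,0
562,0
564,0
566,0
568,0
570,0
572,0
574,0
576,0
578,0
580,0
582,0
584,0
586,0
588,0
590,0
592,0
594,0
596,0
598,0
600,0
602,0
604,0
606,0
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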