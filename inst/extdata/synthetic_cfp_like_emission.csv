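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
346,1e-06
348,1e-06
350,1e-06
352,2e-06
354,2e-06
356,3e-06
358,4e-06
360,6e-06
362,8e-06
364,1.1e-05
366,1.5e-05
368,2e-05
370,2.7e-05
372,3.5e-05
374,4.7e-05
376,6.2e-05
378,8.2e-05
380,0.000108
382,0.00014
384,0.000182
386,0.000236
388,0.000304
390,0.00039
392,0.000499
394,0.000635
396,0.000804
398,0.001015
400,0.001276
402,0.001598
404,0.001996
406,0.002485
408,0.003087
410,0.003828
412,0.004741
414,0.005868
416,0.007265
418,0.009002
420,0.011172
422,0.013894
424,0.01732
426,0.021646
428,0.027111
430,0.034014
432,0.042712
434,0.053622
436,0.067224
438,0.084045
440,0.104644
442,0.129586
444,0.159406
446,0.194562
448,0.235384
450,0.282017
452,0.334368
454,0.392052
456,0.454363
458,0.520256
460,0.588353
462,0.656987
464,0.724262
466,0.788151
468,0.846609
470,0.897696
472,0.939707
474,0.971286
476,0.991521
478,1
480,0.996841
482,0.982668
484,0.958557
486,0.925949
488,0.886537
490,0.84214
492,0.794587
494,0.745601
496,0.696709
498,0.64918
500,0.603983
502,0.561781
504,0.522949
506,0.487601
508,0.455644
510,0.426829
512,0.400802
514,0.377156
516,0.355474
518,0.335359
520,0.316458
522,0.298477
524,0.281185
526,0.264415
528,0.248059
530,0.232056
532,0.216388
534,0.201069
536,0.186132
538,0.171626
540,0.157605
542,0.144123
544,0.131233
546,0.11898
548,0.107402
550,0.096526
552,0.08637
554,0.076941
556,0.068239
558,0.060253
560,0.052966
562,0.046354
564,0.040388
566,0.035034
568,0.030254
570,0.026011
572,0.022264
574,0.018972
576,0.016095
578,0.013594
580,0.011431
582,0.009569
584,0.007975
586,0.006617
588,0.005466
590,0.004495
592,0.00368
594,0.003
596,0.002434
598,0.001967
600,0.001582
602,0.001267
604,0.00101
606,0.000801
608,0.000633
610,0.000498
612,0.00039
614,0.000304
616,0.000236
618,0.000182
620,0.00014
622,0.000107
624,8.2e-05
626,6.2e-05
628,4.7e-05
630,3.5e-05
632,2.7e-05
634,2e-05
636,1.5e-05
638,1.1e-05
640,8e-06
642,6e-06
644,4e-06
646,3e-06
648,2e-06
650,2e-06
652,1e-06
654,1e-06
656,1e-06
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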