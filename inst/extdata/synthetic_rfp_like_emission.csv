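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
388,0
390,0
392,0
394,0
396,0
398,0
400,0
402,0
404,0
406,0
408,0
410,0
412,0
414,0
416,0
418,0
420,0
422,0
424,0
426,0
428,0
430,0
432,0
434,0
436,0
438,0
440,0
442,1e-06
444,1e-06
446,1e-06
448,1e-06
450,2e-06
452,2e-06
454,3e-06
456,4e-06
458,5e-06
460,6e-06
462,8e-06
464,1.1e-05
466,1.4e-05
468,1.8e-05
470,2.2e-05
472,2.9e-05
474,3.6e-05
476,4.6e-05
478,5.8e-05
480,7.3e-05
482,9.2e-05
484,0.000115
486,0.000144
488,0.000179
490,0.000222
492,0.000274
494,0.000339
496,0.000418
498,0.000514
500,0.000632
502,0.000777
504,0.000956
506,0.001177
508,0.001452
510,0.001797
512,0.002233
514,0.002786
516,0.003496
518,0.004409
520,0.005592
522,0.007129
524,0.009126
526,0.011723
528,0.015089
530,0.019435
532,0.025015
534,0.032127
536,0.041116
538,0.052373
540,0.066323
542,0.083419
544,0.104121
546,0.128877
548,0.158094
550,0.192103
552,0.231129
554,0.275247
556,0.324351
558,0.378121
560,0.436004
562,0.497197
564,0.560657
566,0.625115
568,0.689116
570,0.75107
572,0.80932
574,0.862222
576,0.908226
578,0.94596
580,0.974305
582,0.992464
584,1
586,0.996868
588,0.98341
590,0.960335
592,0.928672
594,0.889705
596,0.844903
598,0.795833
600,0.744077
602,0.691158
604,0.638469
606,0.587224
608,0.538421
610,0.492821
612,0.450946
614,0.413092
616,0.379349
618,0.349636
620,0.32373
622,0.301308
624,0.281982
626,0.265328
628,0.250917
630,0.238337
632,0.227206
634,0.217185
636,0.207984
638,0.199362
640,0.191128
642,0.183136
644,0.175281
646,0.167493
648,0.159729
650,0.151972
652,0.14422
654,0.136488
656,0.128796
658,0.121174
660,0.113653
662,0.106265
664,0.099042
666,0.092015
668,0.085211
670,0.078656
672,0.072369
674,0.066369
676,0.060668
678,0.055276
680,0.0502
682,0.045441
684,0.040999
686,0.036871
688,0.033051
690,0.02953
692,0.026298
694,0.023343
696,0.020653
698,0.018213
700,0.016009
702,0.014026
704,0.012248
706,0.010661
708,0.00925
710,0.007999
712,0.006894
714,0.005923
716,0.005072
718,0.004329
720,0.003683
722,0.003123
724,0.00264
726,0.002224
728,0.001867
730,0.001563
732,0.001304
734,0.001084
736,0.000899
738,0.000742
740,0.000611
742,0.000502
744,0.00041
746,0.000335
748,0.000272
750,0.00022
752,0.000178
754,0.000143
756,0.000115
758,9.2e-05
760,7.3e-05
762,5.8e-05
764,4.6e-05
766,3.6e-05
768,2.9e-05
770,2.2e-05
772,1.8e-05
774,1.4e-05
776,1.1e-05
778,8e-06
780,6e-06
782,5e-06
784,4e-06
786,3e-06
788,2e-06
790,2e-06
792,1e-06
794,1e-06
796,1e-06
798,1e-06
800,0
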