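wavelength_nm	mu_a_oxy_cm1	mu_a_deoxy_cm1
400	1424.38985	1194.13134
402	1551.56198	1256.47396
404	1697.66032	1322.61729
406	1874.19717	1393.39265
408	2088.56815	1469.77467
410	2312.68074	1552.90623
412	2494.74299	1644.55073
414	2570.32755	1748.60361
416	2490.08919	1870.35063
418	2270.51069	2016.45143
420	1958.55001	2195.48811
422	1606.45472	2411.47162
424	1263.10846	2636.96687
426	971.28854	2824.52871
428	747.45294	2915.77136
430	589.0334	2854.13455
432	483.84039	2620.59813
434	412.78962	2281.39005
436	362.55284	1913.74501
438	324.92356	1572.04976
440	294.5167	1285.16377
442	268.05914	1059.79434
444	244.85178	884.12029
446	224.70335	746.33217
448	207.41069	637.65885
450	192.77457	551.54945
452	180.5585	482.978
454	170.36171	427.7938
456	161.81512	382.84757
458	154.62029	345.7973
460	148.53243	314.87749
462	143.34769	288.73935
464	138.89351	266.33895
466	135.02128	246.85833
468	131.60084	229.64939
470	128.51638	214.19396
472	125.67863	200.1242
474	123.06588	187.32359
476	120.67289	175.72835
478	118.49507	165.27368
480	116.52847	155.89569
482	114.7698	147.53297
484	113.21649	140.12791
486	111.8667	133.6278
488	110.71941	127.98575
490	109.77441	123.16153
492	109.04021	119.11695
494	108.55731	115.80168
496	108.37471	113.17153
498	108.54332	111.19331
500	109.11745	109.84427
502	110.15672	109.11178
504	111.72831	108.99323
506	113.90968	109.49624
508	116.79194	110.63914
510	120.4841	112.45183
512	125.09587	114.9673
514	130.66893	118.19237
516	137.23335	122.13295
518	144.82609	126.80187
520	153.4884	132.21748
522	163.26298	138.40237
524	174.19078	145.382
526	186.30722	153.18325
528	199.63795	161.83277
530	214.19396	171.35517
532	229.82733	181.748
534	245.72941	192.89909
536	260.70065	204.63047
538	273.29084	216.71126
540	281.88664	228.85225
542	284.87797	240.70379
544	281.24301	251.85825
546	271.76086	261.86436
548	257.84178	270.37958
550	240.96821	277.20939
552	222.76248	282.19399
554	205.42983	285.20858
556	190.78505	286.17411
558	180.13774	285.18702
560	174.56808	282.51425
562	174.84819	278.45202
564	180.46581	273.30531
566	190.89024	267.36641
568	205.79986	260.71102
570	224.90366	253.21973
572	247.23649	244.79267
574	268.96495	235.36347
576	284.25319	224.90366
578	286.48442	213.44798
580	271.29264	201.15158
582	241.35436	188.20566
584	202.43569	174.80816
586	160.64547	161.15824
588	121.26547	147.45076
590	88.19484	133.87123
592	62.71043	120.6611
594	44.23645	108.26548
596	31.41361	97.03099
598	22.78798	87.15326
600	17.13552	78.71628
602	13.50715	71.68127
604	11.134	65.8035
606	9.54163	60.84628
608	8.45166	56.62394
610	7.69261	52.98913
612	7.15287	49.8234
614	6.75502	47.03048
616	6.44134	44.53119
618	6.16585	42.25981
620	5.89033	40.16137
622	5.58947	38.19499
624	5.26738	36.34626
626	4.93415	34.60722
628	4.59856	32.97049
630	4.26798	31.42926
632	3.94834	29.9772
634	3.64415	28.60846
636	3.35866	27.3176
638	3.09404	26.09958
640	2.85149	24.94971
642	2.63152	23.86364
644	2.43403	22.83733
646	2.25856	21.86703
648	2.10437	20.94923
650	1.97058	20.08068
652	1.85597	19.25872
654	1.7581	18.48219
656	1.67464	17.7502
658	1.60369	17.06178
660	1.54367	16.41583
662	1.49325	15.81124
664	1.45133	15.24686
666	1.41701	14.72154
668	1.3895	14.23414
670	1.36817	13.78355
672	1.35248	13.36872
674	1.34196	12.98866
676	1.33622	12.64245
678	1.33494	12.32927
680	1.33784	12.04841
682	1.34466	11.79772
684	1.3552	11.56921
686	1.36927	11.35406
688	1.38669	11.14409
690	1.40731	10.93172
692	1.43096	10.70993
694	1.45751	10.47234
696	1.48679	10.21325
698	1.51865	9.92778
700	1.55291	9.61195
702	1.58941	9.26548
704	1.62811	8.89871
706	1.66903	8.52346
708	1.71215	8.15007
710	1.75745	7.78735
712	1.80493	7.44266
714	1.85455	7.12202
716	1.90627	6.83033
718	1.96007	6.5716
720	2.01588	6.34917
722	2.07363	6.16605
724	2.13325	6.02514
726	2.19463	5.9296
728	2.25768	5.88311
730	2.32225	5.89033
732	2.38821	5.95491
734	2.45538	6.07246
736	2.52358	6.23712
738	2.5926	6.44331
740	2.6622	6.68523
742	2.73215	6.95637
744	2.80215	7.24908
746	2.87192	7.55429
748	2.94112	7.86125
750	3.00943	8.15741
752	3.07652	8.42853
754	3.14231	8.65898
756	3.20678	8.83228
758	3.26992	8.93196
760	3.33172	8.9426
762	3.3922	8.85529
764	3.45137	8.6806
766	3.50926	8.43516
768	3.56591	8.1362
770	3.62136	7.80052
772	3.67568	7.44366
774	3.72894	7.07946
776	3.7812	6.71974
778	3.83255	6.37428
780	3.88309	6.05098
782	3.93292	5.75481
784	3.98213	5.48497
786	4.03086	5.23949
788	4.07922	5.01659
790	4.12735	4.81468
792	4.17538	4.63233
794	4.22346	4.46825
796	4.27174	4.32132
798	4.32038	4.19054
800	4.36956	4.07504
802	4.4194	3.97394
804	4.4699	3.88595
806	4.52101	3.80984
808	4.57267	3.7445
810	4.62484	3.68895
812	4.67745	3.64235
814	4.73045	3.6039
816	4.78378	3.57292
818	4.83736	3.54877
820	4.89113	3.53087
822	4.94503	3.51868
824	4.99897	3.5117
826	5.05287	3.50945
828	5.10667	3.51149
830	5.16027	3.51739
832	5.21359	3.5267
834	5.26655	3.53902
836	5.31904	3.55393
838	5.37099	3.571
840	5.42228	3.58983
842	5.47282	3.60997
844	5.52251	3.631
846	5.57125	3.65246
848	5.61892	3.6739
850	5.66543	3.69485
852	5.71068	3.71491
854	5.75464	3.734
856	5.7973	3.75211
858	5.83867	3.76925
860	5.87874	3.78541
862	5.9175	3.80059
864	5.95496	3.8148
866	5.99112	3.82802
868	6.02598	3.84027
870	6.05955	3.85155
872	6.09183	3.86187
874	6.12282	3.87122
876	6.15255	3.87962
878	6.18102	3.88706
880	6.20823	3.89357
882	6.23421	3.89914
884	6.25897	3.90379
886	6.28252	3.90752
888	6.30488	3.91036
890	6.32606	3.91229
892	6.3461	3.91335
894	6.365	3.91354
896	6.38279	3.91288
898	6.39948	3.91137
900	6.41511	3.90904
902	6.42969	3.9059
904	6.44321	3.90199
906	6.45567	3.89735
908	6.46705	3.89202
910	6.47735	3.88604
912	6.48656	3.87946
914	6.49466	3.87233
916	6.50167	3.86467
918	6.50756	3.85653
920	6.51233	3.84796
922	6.51597	3.839
924	6.51849	3.82969
926	6.51987	3.82006
928	6.52012	3.81016
930	6.51922	3.80004
932	6.51718	3.78973
934	6.514	3.77927
936	6.50966	3.76869
938	6.50418	3.75805
940	6.49756	3.74738
942	6.48978	3.73671
944	6.48086	3.72608
946	6.47079	3.71554
948	6.45959	3.70512
950	6.44724	3.69485
952	6.43376	3.68476
954	6.41921	3.67485
956	6.40362	3.66513
958	6.38706	3.65556
960	6.36958	3.64616
962	6.35123	3.63691
964	6.33207	3.62781
966	6.31214	3.61884
968	6.29151	3.61
970	6.27022	3.60129
972	6.24833	3.59269
974	6.22589	3.5842
976	6.20295	3.57581
978	6.17955	3.56752
980	6.15576	3.55931
982	6.13162	3.55119
984	6.10717	3.54314
986	6.08247	3.53516
988	6.05757	3.52724
990	6.03251	3.51937
992	6.00733	3.51156
994	5.98209	3.50378
996	5.95682	3.49605
998	5.93158	3.48834
1000	5.9064	3.48065
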