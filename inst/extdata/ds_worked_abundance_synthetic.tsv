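mirna	T1	T2	T3	T4	T5	T6	T7	T8	T9	normal_pool
mir205	2800	2700	2600	2500	2400	2300	2200	900	400	1000
mir199a2	2802.8	2702.7	2602.6	2502.5	2402.4	2302.3	2202.2	900.9	400.4	1000
mir103	4108.2	3607.2	2805.6	2505	2204.4	1402.8	1002	801.6	400.8	1000
mir183	4112.3	3610.8	2808.4	2507.5	2206.6	1404.2	1003	802.4	401.2	1000
mir200a	4116.4	3614.4	2811.2	2510	2208.8	1405.6	1004	803.2	401.6	1000
mir203	4120.5	3618	2814	2512.5	2211	1407	1005	804	402	1000
mir222	4124.6	3621.6	2816.8	2515	2213.2	1408.4	1006	804.8	402.4	1000
mirsyn01	4128.7	3625.2	2819.6	2517.5	2215.4	1409.8	1007	805.6	402.8	1000
mirsyn02	4132.8	3628.8	2822.4	2520	2217.6	1411.2	1008	806.4	403.2	1000
mirsyn03	4136.9	3632.4	2825.2	2522.5	2219.8	1412.6	1009	807.2	403.6	1000
mirsyn04	4141	3636	2828	2525	2222	1414	1010	808	404	1000
mirsyn05	4145.1	3639.6	2830.8	2527.5	2224.2	1415.4	1011	808.8	404.4	1000
mirsyn06	4149.2	3643.2	2833.6	2530	2226.4	1416.8	1012	809.6	404.8	1000
mirsyn07	4153.3	3646.8	2836.4	2532.5	2228.6	1418.2	1013	810.4	405.2	1000
mirsyn08	4157.4	3650.4	2839.2	2535	2230.8	1419.6	1014	811.2	405.6	1000
mirsyn09	4161.5	3654	2842	2537.5	2233	1421	1015	812	406	1000
mirsyn10	4165.6	3657.6	2844.8	2540	2235.2	1422.4	1016	812.8	406.4	1000
mirsyn11	4169.7	3661.2	2847.6	2542.5	2237.4	1423.8	1017	813.6	406.8	1000
mirsyn12	4173.8	3664.8	2850.4	2545	2239.6	1425.2	1018	814.4	407.2	1000
mir100	50.95	81.52	101.9	122.28	152.85	203.8	254.75	305.7	1120.9	1000
mir125b	51	81.6	102	122.4	153	204	255	306	1122	1000
mir143	51.05	81.68	102.1	122.52	153.15	204.2	255.25	306.3	1123.1	1000
let7c	51.1	81.76	102.2	122.64	153.3	204.4	255.5	306.6	1124.2	1000
mir141	306.9	286.44	409.2	388.74	368.28	358.05	1227.6	1534.5	2659.8	1000
mir199a	307.2	286.72	409.6	389.12	368.64	358.4	1228.8	1536	2662.4	1000
mir29c	307.5	287	410	389.5	369	358.75	1230	1537.5	2665	1000
mir30c	307.8	287.28	410.4	389.88	369.36	359.1	1231.2	1539	2667.6	1000
mir99a	308.1	287.56	410.8	390.26	369.72	359.45	1232.4	1540.5	2670.2	1000
mir145	308.4	287.84	411.2	390.64	370.08	359.8	1233.6	1542	2672.8	1000
mir101	308.7	288.12	411.6	391.02	370.44	360.15	1234.8	1543.5	2675.4	1000
mir29	309	288.4	412	391.4	370.8	360.5	1236	1545	2678	1000
mir125	309.3	288.68	412.4	391.78	371.16	360.85	1237.2	1546.5	2680.6	1000
mir223	309.6	288.96	412.8	392.16	371.52	361.2	1238.4	1548	2683.2	1000
mir21	4132	3615.5	2789.1	2375.9	464.85	413.2	309.9	247.92	1033	1000
mir10	4136	3619	2791.8	2378.2	465.3	413.6	310.2	248.16	1034	1000
mir30a	4140	3622.5	2794.5	2380.5	465.75	414	310.5	248.4	1035	1000
mir126	4247.6	3729.6	2900.8	2590	2279.2	1450.4	1036	828.8	414.4	1000
mir199b	311.1	290.36	414.8	394.06	373.32	362.95	1244.4	1555.5	2696.2	1000
miscpool	5000.90000000001	15958.78	31766.2	38813.5	50317.88	65146.9	63120.3	65951.22	56167.8	63254
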