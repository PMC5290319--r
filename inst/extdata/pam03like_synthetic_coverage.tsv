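variant	LiM 1	LiM 2	LiM 3	LiM 4	LiM 5	LuM 1	LuM 2	LuM 3	PT 10	PT 11
KRAS_like	294	209	561	2512	39	518	14	30	355	111
ATM_like	207	241	627	4135	16	421	14	39	229	169
var01	306	293	850	3824	38	263	15	40	182	261
var02	490	365	373	2456	24	279	17	22	211	380
var03	440	298	362	2985	40	584	26	35	190	245
var04	210	395	411	4972	14	666	17	26	222	271
var05	294	286	669	4753	34	340	16	31	207	158
var06	345	541	637	3385	17	316	18	27	236	328
var07	222	183	551	5688	25	312	21	50	303	109
var08	213	471	545	4622	32	173	15	24	477	232
var09	183	244	747	2870	32	390	6	27	232	255
var10	516	264	398	4477	22	292	13	52	207	260
var11	396	268	706	5593	22	317	29	58	300	196
var12	294	368	700	1802	6	317	17	22	412	314
var13	287	440	426	4305	17	219	13	50	160	385
var14	323	538	454	5428	19	334	21	34	479	133
var15	290	391	517	2945	27	356	19	22	478	170
var16	247	389	738	4515	26	620	32	17	314	239
var17	293	509	528	2918	22	493	21	52	297	287
var18	263	445	506	5377	21	656	10	61	248	134
var19	182	343	599	2821	37	378	16	16	392	507
var20	320	291	470	5453	34	321	14	48	148	307
var21	215	491	222	1578	32	336	18	22	342	249
var22	233	394	306	5885	9	436	13	52	313	246
var23	679	654	508	6168	29	229	12	22	271	204
var24	286	542	721	4099	15	139	20	31	282	262
var25	296	270	745	1541	32	590	26	63	308	187
var26	285	533	646	4087	12	454	18	24	288	238
var27	460	446	401	4266	21	432	23	14	314	277
var28	248	342	386	2938	18	420	12	50	301	146
var29	321	456	372	5028	22	293	14	22	369	139
var30	131	228	209	2553	17	105	34	31	137	261
var31	393	507	496	2480	20	394	13	26	348	82
var32	206	179	431	2230	18	450	22	38	203	250
var33	216	292	596	1623	39	367	10	42	311	183
var34	590	329	533	3801	41	259	12	22	171	379
var35	281	328	531	2565	28	456	17	27	453	367
var36	297	499	568	3521	18	361	11	12	504	180
var37	135	384	487	5463	20	661	26	53	412	275
var38	351	298	473	5257	19	255	5	38	447	242
var39	373	326	342	2100	14	563	18	13	127	248
var40	394	309	385	4817	22	351	14	29	274	195
var41	316	518	671	1913	30	433	14	30	287	248
var42	345	272	459	3106	19	120	19	33	298	177
var43	397	383	477	5297	18	380	14	42	309	324
var44	281	294	321	3240	31	344	22	17	113	202
var45	332	687	434	1569	13	311	13	34	247	240
var46	167	379	681	4884	24	727	25	18	388	198
var47	338	407	292	6632	43	237	19	58	338	355
var48	415	539	308	4734	20	416	24	4	169	381
var49	391	474	445	2321	34	436	31	17	267	180
var50	437	487	768	3399	36	422	27	9	446	111
var51	186	350	473	4614	9	325	12	9	375	205
var52	161	262	443	4057	18	422	7	22	439	237
var53	464	357	276	4640	37	264	5	22	418	365
var54	260	299	436	3474	19	474	11	30	348	300
var55	367	354	226	5775	16	401	14	31	668	287
var56	206	207	668	2677	18	536	27	39	433	292
var57	346	444	540	4716	31	361	22	17	363	190
var58	206	176	341	3196	27	519	10	30	618	351
var59	401	362	492	3415	40	497	13	16	237	245
var60	326	201	870	6183	19	446	16	26	460	251
var61	181	157	605	4648	12	575	8	35	299	61
var62	581	535	348	4206	43	470	10	17	360	306
var63	152	269	658	3449	28	320	20	31	289	277
var64	431	309	232	3417	45	397	10	28	270	164
var65	174	189	751	3461	19	291	7	28	334	119
var66	360	292	327	2945	16	383	8	36	301	199
var67	295	319	332	5835	28	200	13	21	180	282
var68	488	494	461	7674	20	403	24	25	596	182
var69	317	359	753	7545	8	271	13	39	573	200
var70	226	314	343	6270	41	368	14	35	307	331
var71	357	508	490	3258	32	622	21	31	432	345
var72	377	401	341	3482	14	505	21	25	783	275
var73	310	305	448	5357	31	271	22	21	262	77
var74	409	459	169	2287	36	457	16	16	401	218
var75	377	286	615	6512	27	367	11	30	346	180
var76	276	238	327	3365	16	223	11	18	172	280
var77	410	288	460	2314	26	491	19	25	281	232
var78	283	480	894	4567	22	402	9	16	389	182
var79	241	367	501	5728	44	279	10	45	377	254
var80	240	192	975	7653	13	329	31	54	691	165
var81	152	204	383	9300	36	290	17	10	212	217
var82	114	142	622	3940	13	245	12	29	309	153
var83	146	314	399	2197	22	313	10	23	735	174
var84	440	182	425	6445	15	618	18	33	485	277
var85	183	134	598	6931	25	401	28	27	665	354
var86	81	467	406	5058	19	877	3	39	420	237
var87	246	209	335	5166	30	428	26	47	320	295
var88	450	308	380	3907	35	343	15	27	327	149
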