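variant	LiM 1	LiM 2	LiM 3	LiM 4	LiM 5	LuM 1	LuM 2	LuM 3	PT 10	PT 11
KRAS_like	52	52	127	583	4	59	1	3	61	19
ATM_like	37	45	164	928	2	42	1	6	37	40
var01	57	68	209	841	7	27	1	9	40	41
var02	88	76	92	624	7	35	2	3	40	69
var03	79	54	83	678	7	70	3	7	42	37
var04	40	86	91	1183	0	64	1	3	45	63
var05	54	71	157	1095	5	39	1	4	34	28
var06	70	118	154	743	1	33	4	4	48	59
var07	39	39	127	1275	5	44	3	5	55	23
var08	38	112	135	1009	10	26	1	1	88	51
var09	40	56	191	650	6	47	0	2	44	44
var10	80	44	88	983	2	28	1	4	38	39
var11	64	58	177	1277	2	36	2	7	67	38
var12	53	75	162	395	2	40	0	1	77	64
var13	46	82	106	951	4	20	2	9	33	74
var14	56	114	115	1211	2	33	0	5	103	29
var15	41	77	100	685	1	40	3	3	95	31
var16	45	87	181	1039	2	72	5	1	75	45
var17	52	100	113	685	4	47	5	7	63	51
var18	50	91	123	1165	2	64	0	14	53	25
var19	37	72	156	623	5	32	4	1	66	83
var20	56	57	118	1281	3	24	2	11	34	72
var21	33	95	49	369	8	35	3	6	79	48
var22	39	89	69	1323	1	38	1	2	56	44
var23	102	127	145	1247	1	20	0	2	46	30
var24	61	110	163	960	4	9	2	5	66	47
var25	55	59	171	359	4	60	4	12	57	32
var26	42	113	170	912	2	48	1	5	53	52
var27	85	97	91	938	1	54	3	3	65	59
var28	43	67	92	661	1	38	2	6	74	22
var29	56	110	90	1074	4	35	2	2	79	28
var30	23	54	38	586	2	13	7	4	26	50
var31	88	101	134	604	2	42	1	4	83	16
var32	24	42	99	491	1	59	3	10	44	43
var33	43	69	140	362	9	31	1	6	56	28
var34	106	71	128	859	8	25	0	2	36	60
var35	45	74	124	603	3	45	4	4	89	72
var36	48	108	147	796	1	34	0	4	103	38
var37	23	73	130	1281	6	69	1	10	95	53
var38	54	57	131	1210	3	28	0	3	91	35
var39	3	69	80	486	1	1	0	0	1	38
var40	0	65	102	1137	1	0	0	0	0	28
var41	0	112	169	442	6	0	0	0	1	48
var42	0	51	96	705	1	0	0	0	1	32
var43	0	95	104	1198	3	1	0	0	2	64
var44	0	57	91	720	6	0	0	0	1	36
var45	0	162	96	374	2	1	0	0	1	48
var46	0	76	166	1135	3	2	0	0	1	40
var47	1	89	70	1532	8	1	0	0	0	1
var48	0	129	77	1061	3	0	0	0	0	0
var49	0	94	109	555	5	1	0	0	0	0
var50	0	111	174	774	4	1	0	0	1	0
var51	1	0	130	1021	0	2	0	0	0	0
var52	0	0	91	969	0	0	0	0	0	0
var53	0	0	76	1019	0	0	0	0	0	0
var54	0	61	106	4	1	0	0	0	1	0
var55	1	69	42	6	0	0	0	0	2	0
var56	0	1	3	2	0	54	4	6	0	1
var57	2	2	0	3	1	35	0	2	0	2
var58	0	0	0	6	0	60	2	5	0	2
var59	0	2	3	5	0	43	4	1	0	0
var60	0	1	1	10	0	54	2	4	0	1
var61	1	0	4	4	0	3	1	4	0	0
var62	3	1	0	5	0	2	0	5	0	1
var63	0	0	0	11	0	0	5	8	0	0
var64	70	0	0	7	0	0	0	0	1	1
var65	36	0	0	7	0	1	0	0	1	0
var66	63	0	1	8	0	0	0	0	0	0
var67	0	70	0	9	0	0	0	0	0	0
var68	0	91	1	14	0	1	0	0	0	0
var69	2	0	187	13	0	0	0	0	2	1
var70	1	0	78	16	0	0	0	0	2	0
var71	0	0	1	692	1	4	0	0	0	0
var72	0	2	1	756	0	0	0	0	1	0
var73	0	2	0	4	4	3	0	0	0	0
var74	2	0	0	1	10	1	0	0	1	1
var75	1	0	1	15	8	2	0	0	2	0
var76	2	0	0	8	0	28	0	0	0	0
var77	1	0	0	5	1	42	0	0	0	0
var78	0	2	0	4	0	48	0	0	1	1
var79	0	0	0	13	0	0	0	0	0	0
var80	0	1	1	10	0	0	2	0	1	0
var81	0	1	2	20	0	0	0	2	1	0
var82	0	1	0	7	0	1	0	4	0	0
var83	0	0	0	6	0	1	0	2	0	0
var84	0	0	0	10	0	2	0	0	104	1
var85	0	0	1	10	0	2	0	0	130	0
var86	1	0	0	11	0	1	0	0	84	0
var87	0	0	0	7	0	3	0	0	0	62
var88	1	1	0	11	0	0	0	0	0	27
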