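sample	bmi
sample1	28.84
sample2	22.07
sample3	18.65
sample4	28.46
sample5	25.52
sample6	28.08
sample7	19.44
sample8	22.92
sample9	22
sample10	26.66
sample11	31.36
sample12	25.52
sample13	32.58
sample14	26.98
sample15	35.24
sample16	28.87
sample17	27.78
sample18	24.27
sample19	23.76
sample20	18.45
sample21	27.9
sample22	18.61
sample23	21.57
sample24	25.7
sample25	28.04
sample26	33.61
sample27	22.74
sample28	30.35
sample29	25.38
sample30	21.48
sample31	28.23
sample32	24.42
sample33	31.08
sample34	29.53
sample35	27.06
sample36	20.08
sample37	32.38
sample38	29.79
sample39	20.41
sample40	27.11
sample41	23.19
sample42	27.11
sample43	26.77
sample44	26.18
sample45	22.86
sample46	26.62
sample47	27.73
sample48	22.59
sample49	27.6
sample50	30.75
sample51	24.23
sample52	25.26
sample53	26.25
sample54	22.72
sample55	16.81
sample56	22.59
sample57	20.67
sample58	31.97
sample59	21.17
sample60	22.5
sample61	34.58
sample62	17.47
sample63	22.66
sample64	19.34
sample65	20.68
sample66	23.62
sample67	22.85
sample68	29.06
sample69	29.55
sample70	32.09
sample71	21.22
sample72	24.52
sample73	37.73
sample74	27.08
sample75	24.31
sample76	30.02
sample77	23.04
sample78	31.28
sample79	29.26
sample80	21.67
sample81	17.1
sample82	23.19
sample83	35
sample84	22.93
sample85	29.21
sample86	27.8
sample87	25.15
sample88	19.89
sample89	26.5
sample90	27.38
sample91	24.19
sample92	23.36
sample93	28.08
sample94	27.58
sample95	37.37
sample96	15.26
sample97	27.81
sample98	22.62
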