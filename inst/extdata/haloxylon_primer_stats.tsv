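primer	SB	PB	PPB	PIC	RP	MRP	MI	Hprime
ISSR 7	14	12	85.7	0.46	2.3	0.20	5.5	0.290
ISSR 3	11	10	90.9	0.45	4.9	0.49	4.5	0.266
ISSR 826	21	19	90.5	0.42	6.6	0.35	8.0	0.504
ISSR 5	15	10	66.7	0.40	6.7	0.67	4.0	0.347
ISSR 10	10	10	100.0	0.38	4.1	0.41	3.8	0.262
ISSR 2	16	14	87.5	0.37	6.5	0.46	5.2	0.424
ISSR 8	8	8	100.0	0.34	3.2	0.40	2.7	0.221
ISSR 810	10	8	80.0	0.34	2.8	0.35	2.7	0.260
ISSR 820	11	10	90.9	0.34	4.3	0.43	3.4	0.300
ISSR 17	13	13	100.0	0.26	3.9	0.30	3.4	0.376
ISSR 809	8	7	87.5	0.25	2.2	0.32	1.8	0.233
ISSR 11	9	8	88.9	0.23	2.4	0.31	1.8	0.263
ISSR 18	12	9	75.0	0.22	3.1	0.35	2.0	0.352
ISSR 12	12	12	100.0	0.20	2.8	0.24	2.4	0.360
ISSR 13	10	8	80.0	0.18	1.7	0.22	1.4	0.300
ISSR 23	15	9	60.0	0.18	2.5	0.28	1.6	0.445
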