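tissue	site	n_samples	DAB	B	DAXT	DAT	C	P	total_printed
needle	Zhejiang	40	218	53.7	515.6	181.5	89.9	99.6	1158.3
needle	Fujian	2	78.9	30.2	314.7	122.1	73.5	73.7	693.1
needle	Jiangxi	1	222.2	66.4	497.2	210.4	75.2	119.3	1190.7
needle	Hubei	10	80.9	152.5	545.1	136.5	91.9	115.3	1122.2
root	Zhejiang	22	149.7	287.2	570.7	351.8	293.4	430.7	2083.6
root	Jiangxi	1	70.2	125.9	399.3	164.5	397.1	470.4	1627.4
root	Hubei	10	153.3	172.8	1113.7	287.0	462.7	574.6	2764.2
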