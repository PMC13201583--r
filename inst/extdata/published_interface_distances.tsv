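structure	interface	atp_site	h2i_ps1b
Class1a	D:E	8.713	16.351
Class1a	C:D	8.959	16.46
Class1a	B:C	9.043	16.19
Class1a	A:B	8.961	16.471
Class1a	F:A	8.828	16.305
Class1a	E:F	8.913	16.487
7W1Y	D:E	5.219	7.496
7W1Y	C:D	5.059	7.341
7W1Y	B:C	5.597	7.279
7W1Y	A:B	9.454	19.985
7W1Y	F:A	8.387	12.378
7W1Y	E:F	5.729	7.134
5BK4	D:E	7.049	8.594
5BK4	C:D	6.337	8.68
5BK4	B:C	6.695	7.691
5BK4	A:B	9.071	21.671
5BK4	F:A	10.281	12.446
5BK4	E:F	7.321	10.877
9GJW	D:E	7.414	7.166
9GJW	C:D	5.497	8.547
9GJW	B:C	5.176	7.684
9GJW	A:B	5.696	7.147
9GJW	F:A	7.368	15.688
9GJW	E:F	10.504	16.735
9E2X	D:E	9.086	13.195
9E2X	C:D	9.344	7.121
9E2X	B:C	7.015	6.746
9E2X	A:B	5.259	7.74
9E2X	F:A	6.712	14.124
9E2X	E:F	9.03	14.331
Class2a	D:E	8.339	13.956
Class2a	C:D	8.41	13.9
Class2a	B:C	7.598	12.423
Class2a	A:B	5.973	7.491
Class2a	F:A	5.63	7.662
Class2a	E:F	8.11	14.953
7PMN	D:E	7.744	11.603
7PMN	C:D	6.125	12.507
7PMN	B:C	7.244	7.126
7PMN	A:B	5.217	7.268
7PMN	F:A	5.219	7.235
7PMN	E:F	8.511	21.045
Class2b	D:E	8.483	15.448
Class2b	C:D	8.152	14.074
Class2b	B:C	8.325	12.656
Class2b	A:B	6.186	7.362
Class2b	F:A	5.502	7.479
Class2b	E:F	5.504	7.859
7PMK	D:E	8.365	16.895
7PMK	C:D	6.546	12.843
7PMK	B:C	6.987	11.214
7PMK	A:B	5.143	7.179
7PMK	F:A	5.121	6.967
7PMK	E:F	5.693	7.138
7Z13	D:E	8.488	14.821
7Z13	C:D	7.964	12.973
7Z13	B:C	9.244	13.964
7Z13	A:B	6.733	7.426
7Z13	F:A	5.861	7.455
7Z13	E:F	5.848	7.533
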