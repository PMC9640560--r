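rsid	variant	evidence	structural_coverage	extremely_deleterious	tools_reported
rs9333569	M1V	D:84;VD:77	FALSE	FALSE	NA
rs72552742	E28V	D:77;D:88;D:91	TRUE	FALSE	9
NA	Q42E	D:77;D:81	TRUE	FALSE	3
rs72552740	L49S	VD:77;VD:85;VD:88	TRUE	TRUE	20
rs200591577	L69V	VD:75;VD:83	TRUE	TRUE	18
rs777686348	G71R	VD:77;VD:81	TRUE	TRUE	19
rs281874771	A73V	VD:89	TRUE	FALSE	14
rs1800462	A80P	VD:77;VD:78;VD:87	TRUE	TRUE	20
rs111901354	R82W	VD:74	TRUE	FALSE	14
NA	Y107D	VD:76	TRUE	FALSE	18
rs115106679	E114K	VD:74;VD:86	TRUE	TRUE	7
rs200220210	S125L	D:77;D:88;D:91	TRUE	FALSE	5
rs72552738	C132Y	D:77;D:91;VD:80	TRUE	TRUE	16
rs72552737	G144R	D:77;D:88;D:91;VD:15	TRUE	TRUE	16
rs1800460	A154T	VD:11;VD:73;VD:78;VD:82;VD:87;VD:89	TRUE	TRUE	16
rs112339338	R163C	VD:74	TRUE	FALSE	18
rs144041067	R163H	VD:72;VD:77;VD:81	TRUE	TRUE	15
NA	R163P	VD:75;VD:77	TRUE	TRUE	19
rs201695576	Y166C	D:79	TRUE	FALSE	19
rs74423290	A167G	D:92	TRUE	FALSE	15
rs72556347	F208L	D:90	TRUE	FALSE	10
rs377085266	C212R	VD:83	TRUE	FALSE	18
rs150900439	K238E	D:75;D:77	TRUE	FALSE	5
rs1142345	Y240C	VD:9;VD:11;VD:73;VD:78;VD:82;VD:87	TRUE	TRUE	19
rs1142345	Y240S	VD:20	TRUE	TRUE	18
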