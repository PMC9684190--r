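gene_id	tpm	gene	product
HQ_RS01075	2380	-	Uncharacterized protein
HQ_RS03630	847	sufC	Fe-S cluster assembly ATPase SufC
HQ_RS00075	689	bop1	Bacteriorhodopsin I
HQ_RS03640	601	sufB2	SufB domain protein
HQ_RS03765	419	glpK	Glycerol kinase
HQ_RS03635	767	sufB1	SufB domain protein
HQ_RS12175	692	rps10a	30S ribosomal protein S10a
HQ_RS02125	519	-	CopG domain protein
HQ_RS10230	496	prkA2	Probable PrkA-type serine/threonine protein kinase
HQ_RS03760	404	-	Uncharacterized protein
HQ_RS12180	500	tef1a	Translation elongation factor aEF-1 alpha subunit
HQ_RS01950	651	-	Uncharacterized protein
HQ_RS05300	866	-	ISH9-type transposase ISHwa1
HQ_RS13010	993	-	ISH8-type transposase ISHwa8
HQ_RS02000	560	cspA2	Cold shock protein
HQ_RS00700	515	-	DUF1641 family protein
HQ_RS05510	347	-	IS1341-type transposase
HQ_RS02130	498	ftsZ2	Cell division protein FtsZ, type II
HQ_RS03190	428	livJ1	ABC-type transport periplasmic substrate-binding protein
HQ_RS01835	310	-	IS1341-type transposase
HQ_RS07465	564	sod	Superoxide dismutase (Mn)
HQ_RS09925	759	rps13	30S ribosomal protein S13
HQ_RS01400	725	cspA1	Cold shock protein
HQ_RS05000	533	aldH2	Aldehyde dehydrogenase
HQ_RS00695	480	-	Probable anaerobic dehydrogenase alpha subunit
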