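gene_id	tpm	gene	product
HQ_RS01075	2380	-	Uncharacterized protein
HQ_RS09700	1251	rpl12	50S ribosomal protein L12
HQ_RS12535	1043	fer7	Ferredoxin (2Fe-2S)
HQ_RS13010	993	-	ISH8-type transposase ISHwa8
HQ_RS11475	945	atpH	A-type ATP synthase subunit H
HQ_RS09370	878	rpl29	50S ribosomal protein L29
HQ_RS05300	866	-	ISH9-type transposase ISHwa1
HQ_RS03630	847	sufC	Fe-S cluster assembly ATPase SufC
HQ_RS08655	780	-	CopG domain protein
HQ_RS03635	767	sufB1	SufB domain protein
HQ_RS09925	759	rps13	30S ribosomal protein S13
HQ_RS13890	755	tssA2	Thiosulfate sulfurtransferase
HQ_RS11220	740	-	Uncharacterized protein
HQ_RS01670	738	trxA1	Thioredoxin
HQ_RS02195	732	-	Uncharacterized protein
HQ_RS01400	725	cspA1	Cold shock protein
HQ_RS09285	716	-	Uncharacterized protein
HQ_RS12580	716	-	Uncharacterized protein
HQ_RS06655	712	-	Cupin 2 barrel domain protein
HQ_RS09630	704	rpl8e	50S ribosomal protein L8e
HQ_RS04415	701	cspA3	Cold shock protein
HQ_RS07460	700	-	ISHwa2-type transposase ISHwa2
HQ_RS07640	698	tatA	Sec-independent protein translocase subunit TatA
HQ_RS12175	692	rps10a	30S ribosomal protein S10a
HQ_RS00075	689	bop1	Bacteriorhodopsin I
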