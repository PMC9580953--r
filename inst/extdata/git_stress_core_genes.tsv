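locus_tag	predicted_protein	gene
OHNDKLAL_00510	Putative ornithine decarboxylase	odcl
OHNDKLAL_01838	UDP-galactopyranose mutase	glf
OHNDKLAL_02062	Pyruvate oxidase	pox1
OHNDKLAL_00195	Peptidase M13	pepO
OHNDKLAL_01467	Two-component sensor histidine kinase	arlS
OHNDKLAL_01763	Na+/H+ antiporter NhaC	nhaC
OHNDKLAL_00075	L-lactate dehydrogenase	ldh
OHNDKLAL_00088	S-ribosylhomocysteine lyase	luxS
OHNDKLAL_00120	Serine protease HtrA	htrA
OHNDKLAL_00179	Universal stress protein	usp5
OHNDKLAL_00196	Potassium transporter Kup	kup
OHNDKLAL_00262	Glutamine-hydrolyzing GMP synthase	guaA
OHNDKLAL_00321	CTP synthetase	pyrG
OHNDKLAL_00365	30S ribosomal protein S19	rpsS
OHNDKLAL_00482	Exopolyphosphatase	ppx3
OHNDKLAL_00483	Polyphosphate kinase	ppk
OHNDKLAL_00531	ATP-dependent Clp protease	clpE
OHNDKLAL_00534	Phosphoenolpyruvate--protein phosphotransferase	ptsI
OHNDKLAL_00540	GTP pyrophosphokinase	yjbM
OHNDKLAL_00557	Recombinase recA	recA
OHNDKLAL_00587	Glyceraldehyde-3-phosphate dehydrogenase	gap
OHNDKLAL_00588	Phosphoglycerate kinase	pgk
OHNDKLAL_00595	Phosphate acetyltransferase	pta
OHNDKLAL_00636	Acetate kinase	ackA
OHNDKLAL_00656	F0F1 ATP synthase subunit A	atpB
OHNDKLAL_00657	F0F1 ATP synthase subunit C	atpE
OHNDKLAL_00658	F0F1 ATP synthase subunit A	atpF
OHNDKLAL_00659	F0F1 ATP synthase subunit B	atpH
OHNDKLAL_00660	F0F1 ATP synthase subunit Alfa	atpA
OHNDKLAL_00661	F0F1 ATP synthase subunit gamma	atpG
OHNDKLAL_00662	F0F1 ATP synthase subunit beta	atpD
OHNDKLAL_00663	F0F1 ATP synthase subunit epsilon	atpC
OHNDKLAL_00733	ATP-dependent ClpX protease	clpX
OHNDKLAL_00759	Arginyl-tRNA synthetase	argS
OHNDKLAL_00785	Pyruvate kinase	pyk
OHNDKLAL_00833	ppGpp synthetase	relA
OHNDKLAL_00840	3-oxoacyl-ACP synthase	fabH
OHNDKLAL_01171	Glycine/betaine ABC transporter permease	opuB
OHNDKLAL_01283	Enolase	eno
OHNDKLAL_01301	Molecular chaperone DnaJ	dnaJ
OHNDKLAL_01302	Molecular chaperone DnaK	dnaK
OHNDKLAL_01303	Heat shock protein GrpE	grpE
OHNDKLAL_01333	30S ribosomal protein S2	rpsB
OHNDKLAL_01377	Asp23/Gls24 family envelope stress response protein	yloU
OHNDKLAL_01506	Dihydroorotate dehydrogenase	pyrD
OHNDKLAL_01584	Chaperonin GroEL	groL
OHNDKLAL_01585	Chaperonin GroES	groS
OHNDKLAL_01700	Phosphoglycerate mutase family protein	pgm
OHNDKLAL_01903	Oligoendopeptidase F	pepF
OHNDKLAL_02047	Glucosamine-6-phosphate deaminase	nagB
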