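category_name	code	level	go_name	go_id	network	mips_name	mips_code	n_genes
Metabolism	1	1	metabolic process	GO:0008152		metabolism	01	0
Lipid metabolism	1.1	2	lipid metabolic process	GO:0006629		lipid metabolism	01.06	0
Fatty acid biosynthesis	1.1.1	3	fatty acid biosynthetic process	GO:0006633	NET1006	fatty acid metabolism	01.06.05	0
Amino acid metabolism	1.2	2	cellular amino acid metabolic process	GO:0006520		amino acid metabolism	01.01	0
Secondary metabolism	1.3	2	secondary metabolic process	GO:0019748		secondary metabolism	01.20	0
Flavonoid biosynthesis	1.3.1	3	flavonoid biosynthetic process	GO:0009813	NET1030			0
Transport	2	1	transport	GO:0006810		cellular transport	20	0
Ion transport	2.1	2	ion transport	GO:0006811		ion transport	20.01	0
Copper ion transport	2.1.1	3	copper ion transport	GO:0006825			20.01.11	0
Zinc ion transport	2.1.2	3	zinc ion transport	GO:0006829			20.01.12	0
Transcription	3	1	regulation of transcription	GO:0006355		transcription	11	0
MYB transcription factor family	3.1	2			NET3001			0
Stress response	4	1	response to stress	GO:0006950		cell rescue defense	32	0
Abiotic stress	4.1	2	response to abiotic stimulus	GO:0009628		stress response	32.01	0
Unclassified	5	1					99	0
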