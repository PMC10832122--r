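gene	disease	age_of_onset	motif	gene_region	inheritance	motif_change	unique_motif	svm_score	xgb_score	classification	dataset
AFF2	Fragile X syndrome, FRAXE type	2-10 years	CCG	5'UTR	X-Linked	No	No	0.99	0.91	Pathogenic	Training
AFF3	Intellectual disability associated with fragile site FRA2A	0-7 years	CGG	Intron	Dominant	No	No	0.98	0.64	Pathogenic	Testing
AR	Spinal and bulbar muscular atrophy, Kennedy disease	20-49 years	CAG	Exon	X-Linked	No	No	0.97	1.00	Pathogenic	Training
ARX	Early infantile epileptic encephalopathy	< 1 year	GCG	Exon	X-Linked	No	No	0.99	0.97	Pathogenic	Training
ARX	Partington syndrome	1-3 years	GCN	Exon	X-Linked	No	No	0.98	0.99	Pathogenic	Testing
ATN1	Dentatorubral-pallidoluysian atrophy	1-72 years	CAG	Exon	Dominant	No	No	0.97	0.99	Pathogenic	Training
ATXN1	Spinocerebellar ataxia type 1	13-60 years	CAG	Exon	Dominant	No	No	0.97	0.99	Pathogenic	Training
ATXN10	Spinocerebellar ataxia type 10	12-48 years	ATTCT	Intron	Dominant	No	Yes	0.00	0.00	Benign	Training
ATXN2	Spinocerebellar ataxia type 2	25-50 years	CAG	Exon	Dominant	No	No	0.87	1.00	Pathogenic	Training
ATXN3	Spinocerebellar ataxia type 3, Machado-Joseph disease	10-50 years	CAG	Exon	Dominant	No	No	0.63	1.00	Pathogenic	Training
ATXN7	Spinocerebellar ataxia type 7	0-50 years	CAG	Exon	Dominant	No	No	1.00	1.00	Pathogenic	Training
ATXN8OS	Spinocerebellar ataxia type 8	1-73 years	CTG	3'UTR	Dominant	No	No	0.99	0.90	Pathogenic	Training
BEAN1	Spinocerebellar ataxia type 31	20-72 years	TGGAA	Intron	Dominant	Yes	Yes	0.51	0.04	Pathogenic	Training
C9orf72	Amyotrophic lateral sclerosis, frontotemporal dementia	27-85 years	GGGGCC	Intron	Dominant	No	Yes	0.90	0.94	Pathogenic	Training
CACNA1A	Spinocerebellar ataxia type 6	19-73 years	CAG	Exon	Dominant	No	No	0.92	1.00	Pathogenic	Training
CBL2	Jacobsen syndrome, fragile site FRAX11B	< 1 year	CGG	5'UTR	Dominant	No	No	0.98	0.98	Pathogenic	Testing
CNBP	Myotonic dystrophy type 2	30-40 years	CCTG	Intron	Dominant	No	Yes	0.07	0.00	Benign	Training
COMP	Multiple epiphyseal dysplasia	13 years	GTC	Exon	Dominant	No	Yes	0.96	1.00	Pathogenic	Testing
CSTB	Myoclonic epilepsy of Unverricht and Lundborg	6-15 years	CCCCGCCCCGCG	5'UTR	Recessive	No	Yes	0.83	0.52	Pathogenic	Training
DAB1	Spinocerebellar ataxia type 37	18-64 years	TTTCA	Intron	Dominant	Yes	No	0.00	0.53	Pathogenic	Training
DIP2B	Intellectual developmental disorder, FRA12A type	1 year	CGG	5'UTR	X-Linked	No	No	0.97	1.00	Pathogenic	Testing
DMPK	Myotonic dystrophy type 1	0-70 years	CTG	3'UTR	Dominant	No	No	0.76	0.98	Pathogenic	Training
FGF14	Spinocerebellar ataxia 27B	46-77 years	GAA	Intron	Dominant	No	No	0.02	0.00	Benign	Testing
FMR1	Fragile X syndrome	2-65 years	CGG	5'UTR	X-Linked	No	No	0.97	0.99	Pathogenic	Training
FOXL2	Blepharophimosis, epicanthus inversus, and pitosis	< 1 year	GCC	Exon	Dominant	No	No	0.99	0.99	Pathogenic	Training
FXN	Friedrich ataxia	5-25 years	GAA	Intron	Recessive	No	Yes	0.00	0.01	Benign	Training
GIPC1	Oculopharyngodistal myopathy	10-29 years	CGG	5'UTR	Dominant	No	No	0.95	0.99	Pathogenic	Training
GLS	Glutaminase deficiency	0-1 years	GCA	5'UTR	Recessive	No	No	0.93	1.00	Pathogenic	Training
HOXA13	Hand-foot-genital syndrome 1	< 1 year	GCN	Exon	Dominant	No	No	0.97	1.0	Pathogenic	Testing
HOXA13	Hand-foot-genital syndrome 2	< 1 year	GCG	Exon	Dominant	No	No	1.00	0.99	Pathogenic	Training
HOXA13	Hand-foot-genital syndrome 3	< 1 year	GCN	Exon	Dominant	No	No	1.00	0.99	Pathogenic	Testing
HOXD13	Syndactyly	< 1 year	GCG	Exon	Dominant	No	No	0.83	1.00	Pathogenic	Training
HTT	Huntington disease	10-70 years	CAG	Exon	Dominant	No	No	0.97	1.00	Pathogenic	Training
JPH3	Huntington disease-like 2	12-66 years	CTG	3'UTR	Dominant	No	No	0.56	0.62	Pathogenic	Training
LRP12	Oculopharyngodistal myopathy type 1	7-50 years	CGG	5'UTR	Dominant	No	No	0.98	0.99	Pathogenic	Training
MARCHF6	Familial adult myoclonic epilepsy type 3	10-40 years	TTTCA	Intron	Dominant	Yes	No	0.00	0.01	Benign	Testing
NIPA1	Amyotrophic lateral sclerosis	19-66 years	GCG	Exon	Dominant	No	No	0.98	1.0	Pathogenic	Testing
NOP56	Spinocerebellar ataxia type 36	48-57 years	GGCCTG	Intron	Dominant	No	Yes	0.67	0.66	Pathogenic	Training
NOTCH2NLC	Neuronal intranuclear inclusion disease	16-76 years	GGC	5'UTR	Dominant	No	No	0.88	0.71	Pathogenic	Training
NUTMB-AS1	Oculopharyngeal myopathy with leukoencephalopathy 1	15-40 years	GGC	Exon	Dominant	No	No	0.83	0.04	Pathogenic	Testing
PABPN1	Oculopharyngeal muscular dystrophy	26-65 years	GCG	Exon	Dominant	No	No	0.90	0.80	Pathogenic	Training
PHOX2B	Congenital central hypoventilation syndrome	0-20 years	GCN	Exon	Dominant	No	No	0.71	0.99	Pathogenic	Training
PPP2R2B	Spinocerebellar ataxia type 12	8-55 years	CAG	5'UTR	Dominant	No	No	0.87	1.00	Pathogenic	Training
PRDM12	Hereditary sensory and autonomic neuropathy type VIII	< 1 year	GCC	Exon	Recessive	No	No	0.98	0.98	Pathogenic	Testing
RAPGEF2	Familial adult myoclonic epilepsy type 7	18-37 years	TTTCA	Intron	Dominant	Yes	No	0.02	0.03	Benign	Testing
RFC1	Cerebellar ataxia, neuropathy, and vestibular areflexia syndrome	33-71 years	AAGGG	Intron	Recessive	Yes	Yes	0.01	0.00	Benign	Training
RILPL1	Oculopharyngodistal myopathy type 4	14-27 years	CGG	5'UTR	Dominant	No	No	0.48	0.72	Pathogenic	Testing
RUNX2	Cleidocranial dysplasia	< 1 year	GCN	Exon	Dominant	No	No	1.00	0.99	Pathogenic	Training
SAMD12	Familial adult myoclonic epilepsy type 1	18-50 years	TTTCA	Intron	Dominant	Yes	No	0.94	0.00	Pathogenic	Training
SOX3	X-linked mental retardation	0-9 years	GCC	Exon	X-Linked	No	No	0.95	0.98	Pathogenic	Training
STARD7	Familial adult myoclonic epilepsy type 2	5-60 years	TTTCA	Intron	Dominant	Yes	No	0.05	0.49	Benign	Testing
TBP	Spinocerebellar ataxia type 17	3-55 years	CAG	Exon	Dominant	No	No	0.98	1.00	Pathogenic	Training
TBX1	Tetralogy of Fallot	< 1 year	GCN	Exon	Dominant	No	No	0.96	0.99	Pathogenic	Testing
TCF4	Fuchs endothelial corneal dystrophy 3	32-70 years	CTG	Intron	Dominant	No	No	0.62	0.96	Pathogenic	Training
THAP11	Spinocerebellar ataxia	4-51 years	CAG	Exon	Dominant	No	No	0.96	0.99	Pathogenic	Testing
TNRC6A	Familial adult myoclonic epilepsy type 6	20-70 years	TTTCA	Intron	Dominant	Yes	No	0.00	0.02	Benign	Testing
XYLT1	Baratela-Scott syndrome	< 1 year	GGC	5'UTR	Recessive	No	No	0.99	0.04	Pathogenic	Training
YEATS2	Familial adult myoclonic epilepsy type 4	10-33 years	TTTCA	Intron	Dominant	Yes	No	0.02	0.63	Pathogenic	Testing
ZIC2	Holoprosencephaly-5	< 1 year	GCN	Exon	Dominant	No	No	0.98	1.00	Pathogenic	Training
ZIC3	X-linked VACTERL syndrome	< 1 year	GCN	Exon	X-Linked	No	No	0.97	0.98	Pathogenic	Testing
ZNF713	Autism spectrum disorder associated with fragile site FRA7A	Early	CGG	5'UTR	Dominant	No	No	0.97	0.99	Pathogenic	Testing
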