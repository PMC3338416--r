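gene	protein	oncoscore	regulation
PDGFRA	Alpha-type platelet-derived growth factor receptor	1.000	down
AR	Androgen receptor	1.000	none
TEK	Angiopoietin-1 receptor	1.000	none
BRAF	B-Raf proto-oncogene serine/threonine-protein kinase	1.000	none
EGFR	Epidermal growth factor receptor	1.000	none
ESR1	Estrogen receptor	1.000	none
FLT3	FL cytokine receptor	1.000	none
MET	Hepatocyte growth factor receptor	1.000	up
KIT	Mast/stem cell growth factor receptor	1.000	down
ABL1	Proto-oncogene tyrosine-protein kinase ABL1	1.000	none
SRC	Proto-oncogene tyrosine-protein kinase Src	1.000	none
RAF1	RAF proto-oncogene serine/threonine-protein kinase	1.000	none
FLT1	Vascular endothelial growth factor receptor 1	1.000	none
FLT4	Vascular endothelial growth factor receptor 3	1.000	none
CDK2	Cell division protein kinase 2	0.999	none
NFATC1	Nuclear factor of activated T-cells, cytoplasmic 1	0.999	none
FKBP1A	Peptidyl-prolyl cis-trans isomerase FKBP1A	0.999	down
STAT3	Signal transducer and activator of transcription 3	0.999	none
CDK5	Cell division protein kinase 5	0.998	none
ESR2	Estrogen receptor beta	0.998	none
GSK3A	Glycogen synthase kinase-3 alpha	0.996	none
FGR	Proto-oncogene tyrosine-protein kinase FGR	0.992	none
MAP3K8	Mitogen-activated protein kinase kinase kinase 8	0.984	up
TRPC4	Short transient receptor potential channel 4	0.981	none
HDAC4	Histone deacetylase 4	0.975	none
MAPK10	Mitogen-activated protein kinase 10	0.974	none
TGFBR1	TGF-beta receptor type-1	0.970	none
MDM2	E3 ubiquitin-protein ligase Mdm2	0.966	up
HDAC7	Histone deacetylase 7	0.959	none
PPARG	Peroxisome proliferator-activated receptor gamma	0.959	none
HDAC9	Histone deacetylase 9	0.953	down
SCD	Acyl-CoA desaturase	0.940	up
MAP2K1	Dual specificity mitogen-activated protein kinase kinase 1	0.895	none
HDAC1	Histone deacetylase 1	0.895	none
HDAC6	Histone deacetylase 6	0.895	none
DRD1	D(1A) dopamine receptor	0.866	none
S1PR1	Sphingosine 1-phosphate receptor 1	0.863	none
STAT1	Signal transducer and activator of transcription 1-alpha/beta	0.824	up
KLF5	Krueppel-like factor 5	0.745	down
PARP1	Poly [ADP-ribose] polymerase 1	0.711	none
PIK3CD	Phosphatidylinositol-4,5-bisphosphate 3-kinase	0.708	none
CDK5R1	Cyclin-dependent kinase 5 activator 1	0.701	none
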