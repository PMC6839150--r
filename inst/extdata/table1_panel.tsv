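gene	direction	p	name
AKT2	low	0	V-akt murine thymoma viral oncogene homolog 2
FOSB	low	0.005	FBJ murine osteosarcoma viral oncogene homolog B
CITED4	high	0.009	Cbp/p300-interacting transactivator
CYBA	high	0.012	Cytochrome b-245, alpha polypeptide
JUNB	low	0.013	Jun B proto-oncogene
CYP27B1	high	0.014	Cytochrome P450, family 27, subfamily B, polypeptide 1
FOS	low	0.014	FBJ murine osteosarcoma viral oncogene homolog
NFIX	low	0.027	Nuclear factor I/X
TXNRD1	low	0.041	Thioredoxin reductase 1
USP14	high	0.054	Ubiquitin specific peptidase 14
RIT1	low	0.058	Ras-like without CAAX 1
KEAP1	high	0.0581	Kelch-like ECH-associated protein 1
CYP3A7	high	0.061	Cytochrome P450, family 3, subfamily A, polypeptide 7
TXN	low	0.07	Thioredoxin
GCLC	high	0.07	Glutamate-cysteine ligase, catalytic subunit
AKR7A3	low	0.072	Aldo-keto reductase family 7, member A3
JUN	low	0.074	Jun proto-oncogene
CUL3	low	0.076	Cullin 3
GSTA3	high	0.076	Glutathione S-transferase alpha 3
PMF1	high	0.078	Polyamine-modulated factor 1
PPARG	low	0.106	Peroxisome proliferator-activated receptor gamma
SOD1	high	0.122	Superoxide dismutase 1, soluble
ABCC4	high	0.123	ATP-binding cassette, sub-family C, member 4
GSTM3	low	0.14	Glutathione S-transferase mu 3 (brain)
NOX4	high	0.142	NADPH oxidase 4
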