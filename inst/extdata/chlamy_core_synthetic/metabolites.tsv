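metabolite_id	name	carbon_count	skip_carbon_check
G6P	glucose 6-phosphate	6	FALSE
F6P	fructose 6-phosphate	6	FALSE
GAP	glyceraldehyde 3-phosphate	3	FALSE
PYR	pyruvate	3	FALSE
ACCOA	acetyl-CoA (acetyl skeleton)	2	FALSE
COA	coenzyme A (carrier, skeleton carbon 0)	0	FALSE
OAA	oxaloacetate	4	FALSE
CIT	citrate	6	FALSE
ICIT	isocitrate	6	FALSE
AKG	2-oxoglutarate	5	FALSE
SUCC	succinate	4	FALSE
FUM	fumarate	4	FALSE
MAL	malate	4	FALSE
GLX	glyoxylate	2	FALSE
RU5P	ribulose 5-phosphate	5	FALSE
C1	methylene one-carbon unit (THF-bound)	1	FALSE
CP	carbamoyl phosphate	1	FALSE
ACE	acetate	2	FALSE
NO3	nitrate	0	FALSE
NO2	nitrite (external)	0	FALSE
NO2I	nitrite (internal)	0	FALSE
NH4	ammonium	0	FALSE
GLU	glutamate	5	FALSE
GLN	glutamine	5	FALSE
ASP	aspartate	4	FALSE
SER	serine	3	FALSE
ORN	ornithine	5	FALSE
CITR	citrulline	6	FALSE
ARGSUC	argininosuccinate	10	FALSE
GLY	glycine	2	FALSE
ALA	alanine	3	FALSE
ASN	asparagine	4	FALSE
LYS	lysine	6	FALSE
ARG	arginine	6	FALSE
CO2	carbon dioxide	1	FALSE
ATP	ATP	10	TRUE
ADP	ADP	10	TRUE
NAD	NAD+	21	TRUE
NADH	NADH	21	TRUE
NADP	NADP+	21	TRUE
NADPH	NADPH	21	TRUE
FDOX	ferredoxin (oxidised)	0	FALSE
FDRED	ferredoxin (reduced)	0	FALSE
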