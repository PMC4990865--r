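pattern	category	subtype	priority
annexin	CELL_STRUCTURE		10
actin	CELL_STRUCTURE		11
tubulin	CELL_STRUCTURE		12
myosin	CELL_STRUCTURE		13
profilin	CELL_STRUCTURE		14
tropomyosin	CELL_STRUCTURE		15
prosaposin	METABOLISM	lipid	20
carboxylesterase	METABOLISM	lipid	21
lipase	METABOLISM	lipid	22
chitinase	METABOLISM	carbohydrate	30
mannosidase	METABOLISM	carbohydrate	31
trehalase	METABOLISM	carbohydrate	32
hexosaminidase	METABOLISM	carbohydrate	33
nucleoside diphosphate kinase	METABOLISM	nucleotide	40
carbonic anhydrase	METABOLISM	other	45
cytochrome c	METABOLISM	energy	46
ATP synthase	METABOLISM	energy	47
malate dehydrogenase	METABOLISM	energy	48
heat shock	PROTEIN_MODIFICATION		50
peptidyl-prolyl	PROTEIN_MODIFICATION		51
thiol reductase	PROTEIN_MODIFICATION		52
disulfide isomerase	PROTEIN_MODIFICATION		53
calreticulin	PROTEIN_MODIFICATION		54
endoplasmin	PROTEIN_MODIFICATION		55
neurotrophic factor	PROTEIN_MODIFICATION		56
trypsin	PROTEOLYSIS	protease	60
protease inhibitor|serpin|pacifastin|kazal|propeptide inhibitor|carboxypeptidase inhibitor	PROTEOLYSIS	protease_inhibitor	61
protease|peptidase|carboxypeptidase|cyclotransferase|cathepsin|angiotensin-converting	PROTEOLYSIS	protease	62
chemosensory protein	SIGNAL_TRANSDUCTION		70
phosphatidylethanolamine binding	SIGNAL_TRANSDUCTION		71
renin receptor	SIGNAL_TRANSDUCTION		72
ion transport peptide	SIGNAL_TRANSDUCTION		73
apolipoprotein	TRANSPORT_EXPORT		80
apolipophorin	TRANSPORT_EXPORT		81
lipoprotein receptor	TRANSPORT_EXPORT		82
ribosomal protein	RNA_PROTEIN_SYNTHESIS		90
translation initiation	RNA_PROTEIN_SYNTHESIS		91
cysteine-rich secretory	OTHER	salivary	100
peritrophin	OTHER	chitin_binding	101
dumpy	OTHER	binding	102
selenoprotein	OTHER	sperm_quality	103
thioredoxin	OTHER	oxidoreductase	104
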