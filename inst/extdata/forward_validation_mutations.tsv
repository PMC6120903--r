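site	mutation_type	n_replicates	product
fepA-fes	SNP	34
yjcO-gltP	insertion	34
rph	deletion	27	RNase PH
pyrE-rph	deletion	13
sufB	SNP	4	SufBCD Fe-S cluster scaffold complex
pykF	SNP	3	Pyruvate kinase I
yeaJ	insertion	3	Predicted diguanylate cyclase
sufS	deletion	3	L-cysteine desulfurase
prok	SNP	2	Glycine betaine/proline ABC transporter
rpoB	SNP	2	RNA polymerase sigma 24
sufD	SNP	2	SufBC2D Fe-S cluster scaffold complex
spoT	SNP	1	Guanosine 3-diphosphate 5-triphosphate 3-diphosphatase
nusA	deletion	1	Transcription termination/antitermination L factor
hns-tdk	insertion	1
pykF-ydhZ	SNP	1
acpP-fabG	SNP	1
ybbD	deletion	1	Predicted protein
ybbG	SNP	1	Mechanosensitive channel of miniconductance YbdG
trg	SNP	1	Chemotaxis signaling complex, ribose/galactose/glucose sensing
sufC	SNP	1	SufBC2D Fe-S cluster scaffold complex
ydjJ	SNP	1	Predicted oxidoreductase, Zn-dependent and NAD(P)-binding
prfB	SNP	1	Peptide chain release factor RF2
nikA	SNP	1	Nickel ABC transporter
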