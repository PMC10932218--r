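gene,full_name,function,amplicon_length,accession
ACTB,Beta-Actin,Component of cytoplasmic cytoskeleton,188,HGNC:132
RRN18S,18S ribosomal RNA,Component of small subunit 40S of eukaryotic ribosome complex,120,HGNC:44278
TUBB,Tubulin beta polypeptide,Structural component of microtubules,119,HGNC:20778
GAPDH,Glyceraldehyde-3-phosphate dehydrogenase,Glycolysis: catalyzes D-glyceraldehyde 3-phosphate into 1 3-bisphospho-D-glycerate,151,HGNC:4141
B2M,Beta-2-Microglobulin,Component of MHC1 complex; peptide presentation to the immune system,161,HGNC:914
RPLP,60S acidic ribosomal protein P0,Large subunit of eukaryotic ribosomes,150,HGNC:10371
TBP,TATAA-box binding protein,Initiation of transcription by RNA polymerase II,174,HGNC:11588
GUSB,Beta-Glucuronidase,Hydrolase for degradation of glycosaminoglycan; lysosomal,165,HGNC:4696
HPRT1,Hypoxanthine-guanine phosphoribosyltransferase 1,Purine salvage pathway,94,HGNC:5157
PPIA,Peptidyl-prolyl isomerase A (Cyclophilin A),Cis-trans isomerization of proline imidic peptide bonds,114,HGNC:9253
UBC,Ubiquitin C,Ubiquitination in several cellular functions,240,HGNC:12468
YWHAZ,Tyrosine 3/tryptophan 5-monooxygenase activation protein zeta,Signal transduction via phosphoserine-binding,248,HGNC:12855
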