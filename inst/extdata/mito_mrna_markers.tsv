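gene_id	symbol	biotype
ENSG00000198888	MT-ND1	protein_coding
ENSG00000198763	MT-ND2	protein_coding
ENSG00000198840	MT-ND3	protein_coding
ENSG00000198886	MT-ND4	protein_coding
ENSG00000212907	MT-ND4L	protein_coding
ENSG00000198786	MT-ND5	protein_coding
ENSG00000198695	MT-ND6	protein_coding
ENSG00000198804	MT-CO1	protein_coding
ENSG00000198712	MT-CO2	protein_coding
ENSG00000198938	MT-CO3	protein_coding
ENSG00000198899	MT-ATP6	protein_coding
ENSG00000228253	MT-ATP8	protein_coding
ENSG00000198727	MT-CYB	protein_coding
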