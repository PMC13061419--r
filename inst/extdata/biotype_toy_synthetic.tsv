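gene	biotype
gene0001	protein_coding
gene0002	protein_coding
gene0003	lncRNA
gene0004	protein_coding
gene0005	lncRNA
gene0006	protein_coding
gene0007	protein_coding
gene0008	lncRNA
gene0009	protein_coding
gene0010	protein_coding
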