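# Example locus specification for `orphanscan simulate`
n_orphans: 3
motif: VENN
main_gene_len_nt: 9000
seed: 42
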