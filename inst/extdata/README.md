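`curated_edges_synthetic.sif` is a synthetic, illustrative curated-interaction
edge list (55 protein-protein edges over the 23 default panel genes), generated
programmatically for examples and structural tests. It is not a curated database
export.
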