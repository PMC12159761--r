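# Demo pipeline configuration over the bundled synthetic fixture.
# Paths are relative to the extdata directory; resolve them before use,
# e.g. with system.file("extdata", ..., package = "micronetstab").
table: synthetic_demo_table.tsv
metadata: synthetic_demo_metadata.tsv
tree: synthetic_demo_tree.nwk
plspm_spec: demo_plspm.yml
out_dir: micronetstab_demo_out
rarefy_depth: 34234
rho_min: 0.8
alpha: 0.05
n_permutations: 199
n_null: 50
n_repetitions: 30
seed: 7
stages: [diversity, network, stability]
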