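# Demonstration study: two bamboo-eating focal species against a panel of
# non-herbivore outgroups, one assembly shared by all species. Values mirror
# the package defaults; edit freely.
n_genes: 2000
focal_species: [giant_panda, red_panda]
outgroup_species: [ferret, dog, mouse]
replicates_per_species: 4
n_convergent_up: 100
n_convergent_down: 100
effect_log2fc: 2
nb_dispersion: 0.1
library_size_range: [800000, 1200000]
gene_length_range: [1000, 3000]
n_hypo_promoters: 100
n_hyper_promoters: 100
meth_delta: 0.3
baseline_promoter_meth: 0.4
baseline_body_meth: 0.7
beta_precision: 30
read_depth_mean: 10
promoter_cpg: 20
body_cpg: 20
seed: 104
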