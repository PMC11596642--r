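# Example pipeline configuration: synthetic survey, all stages that do
# not need an initial ratio matrix. Add `f0: path/to/f0.csv` and "chemtax"
# to `stages` to enable group-biomass estimation.
generate: yes
seed: 1
stages: [qa, sizes, pca, hca, network, anova]
beta: 6
cutoff: 0.5
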