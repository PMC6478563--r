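name	value
discovery_cases	215
discovery_male	172
unselected_cases	4370
discovery_age_mean	34.28
discovery_age_sd	16.28
unselected_age_mean	40.01
unselected_age_sd	17.39
discovery_ideation_pct	37.2
unselected_ideation_pct	28.9
n_target_genes	207
n_target_genes_with_literature	18
n_genome_genes	19000
n_literature_genes	755
n_assoc_tests	352
assoc_alpha	0.05
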