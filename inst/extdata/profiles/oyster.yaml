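# Eastern oyster commercial hatchery parameterization.
species_name: oyster
eggs_per_female: 2.0e+07
sperm_egg_ratio: 15
sperm_concentration_per_ml: 1.0e+08
container_volume_ml: 0.5
container_label: 0.5 mL French straw
sperm_volume_per_male_ml: 40
fertilization_rate: 0.20
survival_rate: 0.053
survival_stage_label: spat (post-settlement juvenile, 1-2 months)
target_offspring: 3.3e+06
male_pool_minimum: 0
concentration_context: fresh_and_container
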