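# Hybrid catfish production (male blue catfish x female channel catfish),
# high-throughput hatchery parameterization.
species_name: catfish
eggs_per_female: 1.1e+04
sperm_egg_ratio: 1.35e+05
sperm_concentration_per_ml: 1.0e+09
container_volume_ml: 0.5
container_label: 0.5 mL French straw
sperm_volume_per_male_ml: 32.5
fertilization_rate: 0.67
survival_rate: 0.51
survival_stage_label: swim-up fry (10 d post fertilization)
target_offspring: 1.0e+06
male_pool_minimum: 0
concentration_context: fresh_and_container
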