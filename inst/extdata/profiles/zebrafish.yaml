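# Zebrafish stock-center parameterization (ZIRC-style protocol).
# container_volume_ml is the 0.02 mL sample fill actually frozen, not the
# 0.5 mL nominal cryo-vial capacity; all dose arithmetic uses the fill.
# SOP pools sperm from at least 10 males even when the calculated minimum
# is lower (male_pool_minimum).
species_name: zebrafish
eggs_per_female: 150
sperm_egg_ratio: 2.0e+02
sperm_concentration_per_ml: 1.0e+08
container_volume_ml: 0.02
container_label: cryo-vial, 0.02 mL fill (0.5 mL nominal)
sperm_volume_per_male_ml: 0.0015
fertilization_rate: 0.60
survival_rate: 0.95
survival_stage_label: 28 dpf
target_offspring: 100
male_pool_minimum: 10
concentration_context: fresh_and_container
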