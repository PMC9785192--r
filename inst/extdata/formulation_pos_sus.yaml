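# Posaconazole oral suspension: particle dissolution with
# supersaturation; precipitated drug is recycled to the solid pool.
kind: particle
particle_radius_um: 1.9           # literature (optimized)
unstirred_water_layer_um: 140     # literature (optimized)
drug_density_g_cm3: 0.37          # literature (optimized)
supersaturation_enabled: true
precipitation_halflife_min: 10    # default, configurable
permeability:                     # literature, verbatim unit; a
  value: 5.05e-5                  # "specific" (mucosal-area-referenced)
  unit: cm/min                    # permeability in the source convention
# mucosal villous amplification mapping the specific permeability onto
# the package's smooth-surface segment areas
area_amplification: 40
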