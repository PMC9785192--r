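# Ruxolitinib compound parameters.
name: ruxolitinib
molecular_weight: 306.37      # g/mol, literature
logP: 2.1                     # literature
fu_p: 0.033                   # literature (~96.7% bound)
pka:
  - {value: 4.3, type: base}  # literature (weak base)
solubility_reference:
  value: 1.0                  # mg/mL at pH 7 (highly soluble, BCS I)
  ph: 7.0
solubility_gain_per_charge: 10
partition_method: rodgers_rowland
permeability:                 # identified; high-permeability BCS I
  value: 6.0e-3
  unit: cm/min
clearances:
  - enzyme: CYP3A4            # literature: specific clearance
    kind: first_order_specific_clearance
    value: 0.46               # L/umol/min
  - enzyme: CYP2C9            # literature: specific clearance
    kind: first_order_specific_clearance
    value: 0.65               # L/umol/min
gfr_fraction: 0.0             # renal/biliary excretion negligible
biliary_clearance_per_min: 0.0
interactions: []
blood_plasma_ratio: 1.0
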