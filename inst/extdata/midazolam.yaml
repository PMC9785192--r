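# Midazolam victim-probe parameters, transcribed/linearized from a
# published whole-body model of the CYP3A4 index substrate; packaged as a
# fixture, not re-derived.
name: midazolam
molecular_weight: 325.77
logP: 3.13
fu_p: 0.032
pka:
  - {value: 6.0, type: base}
solubility_reference:
  value: 0.05
  ph: 7.0
solubility_gain_per_charge: 100
partition_method: rodgers_rowland
permeability:
  value: 2.0e-3
  unit: cm/min
clearances:
  - enzyme: CYP3A4
    kind: first_order_specific_clearance
    value: 0.9                # L/umol/min (moderate-extraction probe)
gfr_fraction: 0.0
biliary_clearance_per_min: 0.0
interactions: []
blood_plasma_ratio: 1.0
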