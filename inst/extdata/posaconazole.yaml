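# Posaconazole compound parameters.
# provenance: "literature" = value available in the primary literature;
# "identified" = value identified in this package against published
# exposure metrics; all identified values are configurable.
name: posaconazole
molecular_weight: 700.78      # g/mol, literature
logP: 4.32                    # identified (optimized on i.v. data in source)
fu_p: 0.012                   # identified (~98% plasma protein binding)
pka:
  - {value: 4.6, type: base}  # literature (piperazine)
  - {value: 3.6, type: base}  # literature (triazole)
solubility_reference:         # literature anchor: fed-state/neutral pH
  value: 0.001                # mg/mL at pH 7.0
  ph: 7.0
# gain per charge calibrated so the fasted-stomach anchor (0.79 mg/mL at
# pH 1) is reproduced together with the pH 7 reference
solubility_gain_per_charge: 27.65
partition_method: poulin_theil
permeability: null            # default: calculated from MW and logP
                              # (1.81e-4 cm/min); formulations override
clearances:
  - enzyme: UGT1A4            # linearized kcat process, identified
    kind: first_order_specific_clearance
    value: 0.67               # L/umol/min
gfr_fraction: 1.0             # filtered fraction of unbound drug
biliary_clearance_per_min: 1.66   # identified, 1/min on unbound liver conc
interactions:
  - target_enzyme: CYP3A4
    mechanism: competitive
    ki: 5.22e-3               # umol/L, literature (optimized Ki)
blood_plasma_ratio: 1.0
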