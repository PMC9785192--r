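# Posaconazole delayed-release tablet: Weibull release with enteric
# gastric block; per-segment intestinal solubility adapted (calibration
# target, identified against published day-10 exposure).
kind: weibull
t50_min: 145                      # literature (dissolution time)
shape: 1.67                       # literature (dissolution shape)
lag_min: 30                       # literature (lag time)
gastric_release_blocked: true
supersaturation_enabled: false
precipitation_halflife_min: 10
permeability:                     # literature, verbatim unit (apparent
  value: 4.80e-5                  # CaCo2-cell permeability)
  unit: cm/s
# mapping of the in vitro apparent permeability onto the effective
# in vivo permeability against the package's segment areas
area_amplification: 1.3
intestinal_solubility_mg_mL:
  duodenum: 0.40
  jejunum: 0.40
  ileum: 0.30
  colon: 0.30
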