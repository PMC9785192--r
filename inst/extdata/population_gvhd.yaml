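# Transplant-cohort demographics (healthy physiology, cohort
# demographics): adults of both sexes, middle-aged, wide weight spread.
n: 100
age: {mean: 55, sd: 12, min: 18, max: 75}
weight: {mean: 75, sd: 14, min: 48, max: 115}
height: {mean: 172, sd: 10, min: 150, max: 200}
proportion_female: 0.4
label: gvhd_cohort
seed: 1
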