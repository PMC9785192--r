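# Standard perpetrator regimen: 300 mg once daily, delayed-release tablet.
compound: posaconazole
route: oral
dose_mg: 300
schedule: QD
duration_days: 10
formulation: pos_dr
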