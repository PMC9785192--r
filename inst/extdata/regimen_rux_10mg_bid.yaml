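# Standard victim regimen: 10 mg twice daily, extended-release tablet.
compound: ruxolitinib
route: oral
dose_mg: 10
schedule: BID
duration_days: 10
formulation: rux_er
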