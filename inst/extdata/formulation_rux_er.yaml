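# Ruxolitinib extended-release tablet (integrated Weibull function).
kind: weibull
t50_min: 15                       # literature (dissolution time)
shape: 1.10                       # literature (dissolution shape)
lag_min: 0                        # not printed; identified
gastric_release_blocked: false
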