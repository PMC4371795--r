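prior_low: 0.05
prior_high: 0.25
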