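rule: rescorla-wagner
rule_params:
  alpha: 0.2
  v0: 0.0
  b0_sparse: 0.0
seed: 7
trials:
- trial: 1
  cs: CS+
  us_present: yes
  us_magnitude: 1.2
  probe_present: yes
  phase: acquisition
- trial: 2
  cs: CS+
  us_present: yes
  us_magnitude: 1.2
  probe_present: yes
  phase: acquisition
- trial: 3
  cs: CS+
  us_present: yes
  us_magnitude: 1.2
  probe_present: yes
  phase: acquisition
- trial: 4
  cs: CS+
  us_present: yes
  us_magnitude: 1.2
  probe_present: yes
  phase: acquisition
- trial: 5
  cs: CS+
  us_present: yes
  us_magnitude: 1.2
  probe_present: yes
  phase: acquisition
- trial: 6
  cs: CS+
  us_present: no
  us_magnitude: 0.0
  probe_present: yes
  phase: extinction
- trial: 7
  cs: CS+
  us_present: no
  us_magnitude: 0.0
  probe_present: yes
  phase: extinction
- trial: 8
  cs: CS+
  us_present: no
  us_magnitude: 0.0
  probe_present: yes
  phase: extinction
- trial: 9
  cs: CS+
  us_present: no
  us_magnitude: 0.0
  probe_present: yes
  phase: extinction
- trial: 10
  cs: CS+
  us_present: no
  us_magnitude: 0.0
  probe_present: yes
  phase: extinction
- trial: 11
  cs: CS+
  us_present: no
  us_magnitude: 0.0
  probe_present: yes
  phase: extinction
- trial: 12
  cs: CS+
  us_present: no
  us_magnitude: 0.0
  probe_present: yes
  phase: extinction
- trial: 13
  cs: CS+
  us_present: no
  us_magnitude: 0.0
  probe_present: yes
  phase: extinction
- trial: 14
  cs: CS+
  us_present: no
  us_magnitude: 0.0
  probe_present: yes
  phase: extinction
- trial: 15
  cs: CS+
  us_present: no
  us_magnitude: 0.0
  probe_present: yes
  phase: extinction
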