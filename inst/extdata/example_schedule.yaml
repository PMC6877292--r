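# Default sequential-tracer session: three dyes sharing one detection
# channel, each injected 1 min before its 30-min imaging window.
- name: FITC-dx
  mw_kda: 10.0
  injection_time_min: 0
  window_start_min: 1
  window_end_min: 31
  leak_class: paracellular
- name: AF488
  mw_kda: 0.643
  injection_time_min: 31
  window_start_min: 32
  window_end_min: 62
  leak_class: paracellular
- name: NaFluo
  mw_kda: 0.365
  injection_time_min: 62
  window_start_min: 63
  window_end_min: 93
  leak_class: paracellular
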