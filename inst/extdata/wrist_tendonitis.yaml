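name: wrist_tendonitis
segment:
  t_c: 48
  v_min: 2.0
  v_max: 16.0
collector:
  w: 12.0
  site: wrist
monitoring:
  duration_minutes: 10.0
  opportunity_rate: 1.0
s_min: 100.0
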