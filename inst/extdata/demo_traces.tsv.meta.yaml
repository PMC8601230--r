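mode: strontium
provenance: simulated
eggs:
  NC_001:
    group: NC
    mode: strontium
    replicate: r1
    stimulus_time_s: 0.0
  NC_002:
    group: NC
    mode: strontium
    replicate: r1
    stimulus_time_s: 0.0
  SOV_001:
    group: SOV
    mode: strontium
    replicate: r1
    stimulus_time_s: 0.0
  SOV_002:
    group: SOV
    mode: strontium
    replicate: r1
    stimulus_time_s: 0.0
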