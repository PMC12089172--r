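{
  "war": ["conflict", "combat", "hostilities"],
  "big": ["large", "huge"],
  "cost": ["price", "expense"],
  "car": ["automobile", "vehicle"],
  "fear": ["anxiety", "dread"],
  "happy": ["glad", "joyful"],
  "job": ["work", "employment"],
  "risk": ["hazard", "danger"],
  "fast": ["quick", "rapid"],
  "responsibility": ["accountability"],
  "transport": ["transit"],
  "pollution": ["contamination"],
  "freedom": ["liberty"],
  "trust": ["confidence"]
}
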