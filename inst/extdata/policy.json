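{
  "comment": "National delta-NTCP thresholds in percentage points by CTCAE grade; inclusive (>=) comparison.",
  "single": { "2": 10, "3": 5, "4": 2 },
  "summed": { "2": 15, "3": 7.5, "4": 3 }
}
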