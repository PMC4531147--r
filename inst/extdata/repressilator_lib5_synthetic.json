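{
  "schema_version": "1",
  "comment": "Synthetic five-component repression library; not measured data.",
  "components": [
    { "name": "Q1", "gubs": "LacI o-> !TetR_lite" },
    { "name": "Q2", "gubs": "CI o-> !LacI" },
    { "name": "Q3", "gubs": "TetR_lite o-> !CI" },
    { "name": "Q4", "gubs": "TetR_lite o-> !GFP" },
    { "name": "Q5", "gubs": "AraC o-> !GFP" }
  ]
}
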