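[
  {
    "module_id": "reductive_acetyl_coa",
    "description": "Reductive acetyl-CoA (Wood-Ljungdahl) pathway, encoded as ten single-KO components in table row order",
    "components": [
      ["K00198"],
      ["K05299"],
      ["K01938"],
      ["K01491"],
      ["K00297"],
      ["K15023"],
      ["K14138"],
      ["K00197"],
      ["K00194"],
      ["K00600"]
    ]
  }
]
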