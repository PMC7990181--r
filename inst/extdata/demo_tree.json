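{
  "nodes": ["normal", "C1", "C2"],
  "root": "normal",
  "parent": [
    {
      "child": "C1",
      "parent": "normal"
    },
    {
      "child": "C2",
      "parent": "normal"
    }
  ],
  "edge_counts": [
    {
      "child": "C1",
      "snv": 5,
      "indel": 0,
      "cna": 1,
      "sv": 1,
      "_row": "C1"
    },
    {
      "child": "C2",
      "snv": 1,
      "indel": 0,
      "cna": 0,
      "sv": 0,
      "_row": "C2"
    }
  ],
  "prevalence": [
    {
      "node": "normal",
      "value": 0.315859547109063
    },
    {
      "node": "C1",
      "value": 0.412760006342739
    },
    {
      "node": "C2",
      "value": 0.271380446548198
    }
  ]
}
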