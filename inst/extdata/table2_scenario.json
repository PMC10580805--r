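{
  "label": "five-issue-worked-example",
  "issues": [
    {
      "name": "Cost",
      "lo": 0,
      "hi": 8,
      "step": 0.08
    },
    {
      "name": "Effective",
      "lo": 1,
      "hi": 10,
      "step": 0.09
    },
    {
      "name": "Side-effects",
      "lo": 0,
      "hi": 1,
      "step": 0.01
    },
    {
      "name": "Risk",
      "lo": 0,
      "hi": 1,
      "step": 0.01
    },
    {
      "name": "Convenience",
      "lo": 1,
      "hi": 10,
      "step": 0.09
    }
  ],
  "pa": {
    "weights": [0.2, 0.1, 0.2, 0.3, 0.2],
    "membership": [
      [2, 3.5, 4, 6, 1],
      [8, 9, 10, 10, 1],
      [0, 0.05, 0.1, 0.2, 1],
      [0, 0.02, 0.05, 0.15, 1],
      [8, 9, 10, 10, 1]
    ]
  },
  "da": {
    "weights": [0.25, 0.15, 0.3, 0.2, 0.1],
    "membership": [
      [4, 5, 7, 8, 1],
      [6, 7, 8, 9, 1],
      [0.1, 0.15, 0.2, 0.25, 1],
      [0.05, 0.1, 0.15, 0.2, 1],
      [6, 7, 8, 9, 1]
    ]
  }
}
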