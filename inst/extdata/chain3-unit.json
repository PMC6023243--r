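{
  "states": [
    {
      "id": 1,
      "label": "S1",
      "measurement": 0
    },
    {
      "id": 2,
      "label": "S2",
      "measurement": 0
    },
    {
      "id": 3,
      "label": "S3",
      "measurement": 1
    }
  ],
  "edges": [
    {
      "from": 1,
      "to": 2,
      "rate": 1
    },
    {
      "from": 2,
      "to": 1,
      "rate": 1
    },
    {
      "from": 2,
      "to": 3,
      "rate": 1
    },
    {
      "from": 3,
      "to": 2,
      "rate": 1
    }
  ],
  "n_walkers": 1
}
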