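{
  "states": [
    {
      "id": 1,
      "label": "AR",
      "measurement": 1
    },
    {
      "id": 2,
      "label": "A2R",
      "measurement": 1
    },
    {
      "id": 3,
      "label": "A2T",
      "measurement": 0
    },
    {
      "id": 4,
      "label": "AT",
      "measurement": 0
    },
    {
      "id": 5,
      "label": "T",
      "measurement": 0
    }
  ],
  "edges": [
    {
      "from": 2,
      "to": 1,
      "rate": 0.00066666666666666664
    },
    {
      "from": 1,
      "to": 2,
      "rate": 0.25
    },
    {
      "from": 3,
      "to": 2,
      "rate": 15
    },
    {
      "from": 2,
      "to": 3,
      "rate": 0.5
    },
    {
      "from": 3,
      "to": 4,
      "rate": 4
    },
    {
      "from": 4,
      "to": 3,
      "rate": 0.25
    },
    {
      "from": 4,
      "to": 1,
      "rate": 0.014999999999999999
    },
    {
      "from": 1,
      "to": 4,
      "rate": 3
    },
    {
      "from": 4,
      "to": 5,
      "rate": 2
    },
    {
      "from": 5,
      "to": 4,
      "rate": 0.050000000000000003
    }
  ],
  "n_walkers": 500
}
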