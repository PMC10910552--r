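{
  "protein_length": 585,
  "regions": [
    {
      "name": "IC1",
      "class": "IC",
      "start": 1,
      "end": 30
    },
    {
      "name": "TM1",
      "class": "TM",
      "start": 31,
      "end": 50
    },
    {
      "name": "EC1",
      "class": "EC",
      "start": 51,
      "end": 70
    },
    {
      "name": "TM2",
      "class": "TM",
      "start": 71,
      "end": 94
    },
    {
      "name": "IC2",
      "class": "IC",
      "start": 95,
      "end": 234
    },
    {
      "name": "TM3",
      "class": "TM",
      "start": 235,
      "end": 257
    },
    {
      "name": "EC2",
      "class": "EC",
      "start": 258,
      "end": 268
    },
    {
      "name": "TM4",
      "class": "TM",
      "start": 269,
      "end": 287
    },
    {
      "name": "IC3",
      "class": "IC",
      "start": 288,
      "end": 585
    }
  ],
  "subregions": {
    "ca_binding": [293, 308],
    "ef_hand": [312, 323],
    "ic3_proximal": [288, 323]
  }
}
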