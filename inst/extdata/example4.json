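{
  "name": "example4",
  "note": "3-region scenario with every event class active",
  "regions": [
    "A",
    "B",
    "C"
  ],
  "rates": {
    "w": {
      "A": 0.09,
      "B": 0.06,
      "C": 0.07
    },
    "e": {
      "A": 0.002,
      "B": 0.003,
      "C": 0.001
    },
    "d": {
      "B>A": 0.006,
      "C>A": 0.003,
      "A>B": 0.006,
      "C>B": 0.001,
      "A>C": 0.003,
      "B>C": 0.001
    },
    "b": {
      "A|B": 0.04,
      "A|C": 0.04,
      "B|C": 0.04,
      "A|BC": 0.04,
      "AC|B": 0.04,
      "AB|C": 0.04
    }
  },
  "init": {
    "total": [
      40
    ],
    "frequencies": {
      "A": 0,
      "B": 0,
      "C": 0,
      "AB": 0.25,
      "AC": 0.25,
      "BC": 0.25,
      "ABC": 0.25
    }
  },
  "run": {
    "t_max": 10,
    "n_steps": 1000,
    "replicates": 1000
  }
}
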