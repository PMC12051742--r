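{
  "name": "gws",
  "config": {
    "mutation_rate": 3.18e-09,
    "generation_time": 5.79,
    "rng_seed": null
  },
  "populations": [
    {
      "name": "SPA",
      "n_diploid_samples": 15,
      "ne_present": 50000,
      "growth_rate": 0,
      "growth_start_time": 0
    },
    {
      "name": "EURw",
      "n_diploid_samples": 15,
      "ne_present": 200000,
      "growth_rate": 0.000235,
      "growth_start_time": 3100
    },
    {
      "name": "EURns",
      "n_diploid_samples": 15,
      "ne_present": 400000,
      "growth_rate": 0.000254,
      "growth_start_time": 34500
    },
    {
      "name": "IRQ",
      "n_diploid_samples": 5,
      "ne_present": 20000,
      "growth_rate": 0,
      "growth_start_time": 0
    },
    {
      "name": "ANCcc",
      "n_diploid_samples": 0,
      "ne_present": 100000,
      "growth_rate": 0,
      "growth_start_time": 0
    },
    {
      "name": "ANChc",
      "n_diploid_samples": 0,
      "ne_present": 100000,
      "growth_rate": 0,
      "growth_start_time": 0
    },
    {
      "name": "ANC",
      "n_diploid_samples": 0,
      "ne_present": 100000,
      "growth_rate": 0,
      "growth_start_time": 0
    }
  ],
  "splits": [
    {
      "time": 34500,
      "derived_pop": "SPA",
      "ancestral_pop": "ANCcc"
    },
    {
      "time": 34500,
      "derived_pop": "EURw",
      "ancestral_pop": "ANCcc"
    },
    {
      "time": 131000,
      "derived_pop": "IRQ",
      "ancestral_pop": "ANChc"
    },
    {
      "time": 131000,
      "derived_pop": "EURns",
      "ancestral_pop": "ANChc"
    },
    {
      "time": 504000,
      "derived_pop": "ANCcc",
      "ancestral_pop": "ANC"
    },
    {
      "time": 504000,
      "derived_pop": "ANChc",
      "ancestral_pop": "ANC"
    }
  ],
  "migration_epochs": [
    {
      "start_time": 0,
      "end_time": 34500,
      "donor": "SPA",
      "recipient": "EURw",
      "rate": 0.000316
    },
    {
      "start_time": 0,
      "end_time": 34500,
      "donor": "EURw",
      "recipient": "SPA",
      "rate": 0.000169
    },
    {
      "start_time": 0,
      "end_time": 131000,
      "donor": "IRQ",
      "recipient": "EURns",
      "rate": 5.68e-06
    },
    {
      "start_time": 0,
      "end_time": 131000,
      "donor": "EURns",
      "recipient": "IRQ",
      "rate": 4.52e-05
    },
    {
      "start_time": 0,
      "end_time": 20000,
      "donor": "EURns",
      "recipient": "EURw",
      "rate": 0.000694
    },
    {
      "start_time": 0,
      "end_time": 20000,
      "donor": "EURw",
      "recipient": "EURns",
      "rate": 0.000129
    }
  ]
}
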