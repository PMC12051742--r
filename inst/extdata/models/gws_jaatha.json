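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
      "growth_rate": 3.74e-05,
      "growth_start_time": 28000
    },
    {
      "name": "EURns",
      "n_diploid_samples": 15,
      "ne_present": 400000,
      "growth_rate": 8.74e-05,
      "growth_start_time": 17800
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
      "time": 31200,
      "derived_pop": "SPA",
      "ancestral_pop": "ANCcc"
    },
    {
      "time": 31200,
      "derived_pop": "EURw",
      "ancestral_pop": "ANCcc"
    },
    {
      "time": 107000,
      "derived_pop": "IRQ",
      "ancestral_pop": "ANChc"
    },
    {
      "time": 107000,
      "derived_pop": "EURns",
      "ancestral_pop": "ANChc"
    },
    {
      "time": 428000,
      "derived_pop": "ANCcc",
      "ancestral_pop": "ANC"
    },
    {
      "time": 428000,
      "derived_pop": "ANChc",
      "ancestral_pop": "ANC"
    }
  ],
  "migration_epochs": [
    {
      "start_time": 0,
      "end_time": 31200,
      "donor": "SPA",
      "recipient": "EURw",
      "rate": 9.7e-05
    },
    {
      "start_time": 0,
      "end_time": 31200,
      "donor": "EURw",
      "recipient": "SPA",
      "rate": 9.52e-05
    },
    {
      "start_time": 0,
      "end_time": 107000,
      "donor": "IRQ",
      "recipient": "EURns",
      "rate": 8.82e-06
    },
    {
      "start_time": 0,
      "end_time": 107000,
      "donor": "EURns",
      "recipient": "IRQ",
      "rate": 4.41e-05
    },
    {
      "start_time": 0,
      "end_time": 30600,
      "donor": "EURns",
      "recipient": "EURw",
      "rate": 0.000242
    },
    {
      "start_time": 0,
      "end_time": 30600,
      "donor": "EURw",
      "recipient": "EURns",
      "rate": 9.32e-05
    }
  ]
}
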