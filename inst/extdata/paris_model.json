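{
  "model_id": "PARIS",
  "components": {
    "atpase": {
      "AAA_15": 32,
      "AAA_21": 27
    },
    "partner": {
      "DUF4435": 27
    }
  },
  "fusion_profiles": {
    "AAA_15+DUF4435": 80,
    "AAA_21+DUF4435": 20
  },
  "loner_allowed_for_fusion": true,
  "max_intervening_genes": 2
}
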