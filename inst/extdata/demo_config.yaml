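# generator configuration for simulate_from_config(): a cohort with one
# planted epistatic risk pair on the default nine loci
"n": 300
seed: 42
noise_sd: 3
base_rate: 0.125
effects:
  - kind: epistatic
    loci: [CLOCK3111, CRY2]
    levels: [TC, GA]
    beta: 1.2
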