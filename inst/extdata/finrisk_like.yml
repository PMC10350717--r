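# Default pipeline configuration: synthetic five-wave survey, projections
# for two future years, hold-out validation against the final wave.
seed: 20211214
m: 10
iterations: 5
level: 0.95
years: [2020, 2025]
size: 2000
holdout_year: 2017
models:
  smoking: ["sex", "age", "rcs(year, 2)", "area", "education", "marital",
            "obesity", "hypertension"]
  obesity: ["sex", "age", "year", "year:age", "area", "education", "marital",
            "smoking", "hypertension"]
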