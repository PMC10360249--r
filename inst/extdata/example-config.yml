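# Example pipeline configuration (YAML dialect: 2-space indentation,
# scalars and inline lists only). Values omitted here fall back to
# default_pipeline_config().
seed: 7
crs: "local-metres"
simulate:
  enabled: true
  n_areas: 100
adjacency:
  scheme: queen
zones:
  primary: 1
  intermediate: 2
idw:
  power: 2
  quintiles: false
model:
  covariates: [migrant_rate, pop_under15, imp, pea, pm10]
  chains: 4
  draws: 1000
  burnin: 8000
  thin: 8
  prior_u: [0.1, 0.1]
  prior_st: [0.001, 0.001]
thresholds:
  exceedance: 1.5
  probability: 0.8
  vif: 5
  dic_equivalence: 2
select:
  enabled: true
  chains: 2
  draws: 300
  burnin: 600
paths:
  output_dir: bym_out
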