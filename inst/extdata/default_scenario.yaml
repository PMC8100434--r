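# Default synthetic-cohort scenario: a merged ICI-treated NSCLC-like
# discovery cohort. GoodBenefit (NOTCH+/co-DDR+) hazard ratio 0.34 on an
# exponential PFS with BadBenefit median 3.6 months; ~70% of GoodBenefit
# patients achieve durable clinical benefit.
n_samples: 106
p_gene: 0.01
enrich_mult: 5
p_latent: 0.45
lambda_bg: 80
bg_mult_latent: 1.6
planted_hr: 0.34
baseline_hazard: 0.19254
censor_rate: 0.02
admin_cutoff: 40
dcb_prob:
  GoodBenefit: 0.70
  BadBenefit: 0.35
tnb_ratio: 0.1
n_genes: 1200
delta: 1.5
seed: 42
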