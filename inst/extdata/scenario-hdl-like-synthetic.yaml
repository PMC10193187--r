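# Synthetic scenario sized like a lipoprotein-cholesterol exposure in a
# large biobank GWAS: 534 independent instruments jointly explaining about
# 12% of an SD-scaled trait, against a case-control outcome of 39,106 cases
# and 401,577 controls. All values are synthetic; nothing here is real data.
n_snv: 534
theta: 0.07          # log odds of the outcome per SD of the exposure
beta_exp_mean: 0
beta_exp_sd: 0.025
maf_range: [0.05, 0.5]
n_exp: 403943
n_out_case: 39106
n_out_control: 401577
pleiotropy:
  mode: balanced
  sd: 0.001
  invalid_fraction: 1
seed: 1
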