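# Base-case model configuration. Probabilities are unitless; rates carry
# their unit in the key name; costs are 2016/17 GBP. Table-valued inputs
# live in the sibling CSV files listed under `tables:` (synthetic fixtures
# regenerated by scripts/make_fixtures.R).
prevalence_ls: 0.039
overall_gene_mix:
  MLH1: 0.169
  MSH2: 0.246
  MSH6: 0.477
  PMS2: 0.108
ihc:
  sensitivity: 0.944
  specificity: 0.748
  failure_rate: 0.037
msi:
  sensitivity: 0.903
  specificity: 0.771
  failure_rate: 0.019
# probability an IHC-positive tumour shows the dMLH1 staining pattern
staining_p_dmlh1:
  mlh1_carrier: 0.89
  other_carrier: 0.006
  sporadic: 0.83
meth_after_dmlh1:
  sensitivity: 0.95
  specificity: 0.936
meth_after_msi:
  sensitivity: 0.95
  p_meth_other_carrier: 0.07142857142857142
  p_meth_sporadic: 0.67
germline:
  diagnostic_sensitivity: 0.90
  diagnostic_specificity: 1.0
  predictive_accuracy: 1.0
uptake:
  p_attend_counselling: 0.55
  p_decline_test: 0.10
  relative_uptake: 1.0
  # long-term adherence to biennial colonoscopy without a confirmed
  # molecular diagnosis (putative-LS pathway); synthetic placeholder
  p_surveillance_unresolved: 0.5
ec_mortality_ls_per_1000py: 4.0
# surveillance colonoscopy ~halves LS CRC incidence (observational
# estimate; supplementary source value unavailable, placeholder)
surveillance_incidence_hr: 0.38
crc_mortality_hr_ls_stage123: 0.66
# stage at diagnosis I-IV; placeholder splits flagged in the vignette
# (screen-detected cancers present earlier than symptomatic ones)
stage_distribution:
  surveillance: [0.50, 0.31, 0.13, 0.06]
  none: [0.13, 0.30, 0.29, 0.28]
stage4_utility_multiplier: 0.79
costs:
  ihc_gbp: 210
  msi_gbp: 202
  methylation_gbp: 136
  counselling_offer_gbp: 27
  relative_referral_gbp: 36
  pretest_counselling_proband_gbp: 347
  pretest_counselling_relative_gbp: 172
  posttest_counselling_gbp: 133
  diagnostic_test_gbp: 755
  predictive_test_gbp: 166
  colonoscopy_gbp: 583
colonoscopy_interval_years: 2.1
# surveillance (and its stage-shift benefit) runs to this age, per
# guideline practice for colonoscopic surveillance programmes
surveillance_stop_age: 75
discount_rate_annual: 0.035
wtp_threshold_gbp: 20000
n_probands: 1000
relatives_per_proband: 6
proband_age: 60
relative_age: 54
horizon_age: 100
cycle_length_months: 1
failure_policy: refer
tables:
  gene_mix_by_age: gene_mix_by_age.csv
  prevalence_by_age: prevalence_by_age.csv
  ec_mortality_sporadic: ec_mortality_sporadic.csv
  crc_incidence_ls: crc_incidence_ls.csv
  crc_incidence_general: crc_incidence_general.csv
  crc_mortality_general: crc_mortality_general.csv
  crc_costs: crc_costs.csv
  utilities: utilities.csv
  life_table: life_table.csv
  ec_age_distribution: ec_age_distribution.csv
  relative_age_distribution: relative_age_distribution.csv
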