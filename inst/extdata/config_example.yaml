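# Example pipeline configuration covering every key.
# With no `inputs` block the simulate stage generates a synthetic cohort
# and the later stages consume it.

seed: 7

# inputs:                      # uncomment to analyse real record files
#   products: data/products.txt
#   products_dialect: orange_book   # or "csv"
#   monographs: data/monographs.csv
#   sales: data/sales.csv
#   price_curve: data/price_curve.csv   # competition-to-price curve

simulate:
  n_drugs: 982
  n_classes: 30
  class_effect_sd: 0.3
  monograph_product_prev: 0.403
  monograph_substance_prev: 0.749
  frac_monograph_before_first: 0.51
  true_or_any_generic: 0.64
  true_irr_count: 1.53
  true_hr_gap23: 0.99
  true_hr_gap12: 0.88
  baseline_any_generic_prob: 0.65
  baseline_count_mean: 1.7
  count_dispersion: 0.65
  gap_time_scale_days: 260
  exposure_timing: before_first

cascade:
  pre_approval_cut_year: 1982
  loe_cut_year: 1998

savings:
  years: [2015, 2016]
  exposure: before_first       # or "any" (sensitivity)

study_end: 2018-04-03
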