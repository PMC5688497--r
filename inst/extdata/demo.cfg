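# Demo pipeline configuration: simulate a small multi-survey panel of birth
# histories, aggregate, fit all model variants, and run the A/B/C scenarios.
stages = simulate,aggregate,fit,predict
seed = 7
n_surveys = 20
n_women = 400
n_countries = 7
variants = m1,m2,m3
predict_variant = m3
scenarios = A,B,C
delta_mcpr_pp = 10
fallback = zero
zero_rule = continuity
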