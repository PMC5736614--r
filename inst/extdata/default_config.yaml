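# Default pipeline configuration.
# cohort: arguments of cohort_config() (omitted fields keep package defaults,
# which emulate the published study design: 271 subjects, ages 8-25 at wave 1,
# three biannual waves, retention 0.86, inter-variable correlation 0.66).
cohort:
  n_subjects: 271
behavioral:
  ages: [9.0, 13.0, 17.0, 21.0, 25.0]
mc:
  alpha_family: 0.05
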