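# End-to-end demo: simulate a wild-type cohort, a pendrin-KO cohort and a
# PRM fixture, derive phenotypes, quantify both acquisition modes, and
# integrate proteome with phenotype.
seed: 1
stages:
  - simulate
  - ephys
  - quantify_targeted
  - quantify_untargeted
  - integrate
simulate:
  n_tubules: 12
  ko_n_per_group: 5
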