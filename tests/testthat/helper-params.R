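# shared fixtures: the published ASD parameter sets
pf <- param_library("asd_female")
pm <- param_library("asd_male")

# independent closed-form evaluation of the prevalence, used as an oracle
# (kept separate from susceptible_prevalence on purpose)
ps_ref <- function(t, p) (1 - exp(-p$k1 * p$r * t))^p$m1 *
  (1 - exp(-p$k2 * p$r * t))
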