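# shared fixtures, built in code

ref_config <- reference_parameters()

# a disease-free configuration: no starting ulcers, no onset
disease_free_config <- function() {
  cfg <- reference_parameters()
  cfg$probabilities$prevalence$value <- 0
  cfg$probabilities$incidence_risk$value <- 0
  cfg
}

# strip all uncertainty: Beta specs removed, price sds zeroed
degenerate_config <- function() {
  cfg <- reference_parameters()
  for (nm in names(cfg$probabilities)) {
    cfg$probabilities[[nm]]$alpha <- NA_real_
    cfg$probabilities[[nm]]$beta <- NA_real_
  }
  for (nm in names(cfg$costs)) cfg$costs[[nm]]$cad_sd <- 0
  cfg
}

set_cost_usd <- function(cfg, nm, usd) {
  cfg$costs[[nm]]$usd <- usd
  cfg$costs[[nm]]$cad_mean <- usd / cfg$fx_rate
  cfg
}
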