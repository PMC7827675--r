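# Shared fixtures: frameworks and farm bundles built in code.

default_fw <- load_framework()
excluded_fw <- apply_exclusions(default_fw, default_exclusions())

# a farm bundle whose indicator scores cover every indicator directly
# (adapter indicators included), bypassing the adapters
constant_farm <- function(percent, framework = excluded_fw,
                          farm_id = "farm-const") {
  list(
    farm_id = farm_id, system_type = "NS",
    indicator_scores = tibble::tibble(
      indicator_id = framework$indicators$id,
      percent = percent,
      timeframe = "current", data_type = "primary",
      methodology = "safa_conform"))
}

# random flat hierarchy: n_sub subthemes, each holding a few indicator
# percents; returns the structure plus an independently computed recursive
# mean (the oracle)
random_hierarchy <- function(n_sub_max = 4, n_ind_max = 4) {
  n_sub <- sample(1:n_sub_max, 1)
  subthemes <- lapply(seq_len(n_sub), function(i) {
    n_ind <- sample(1:n_ind_max, 1)
    round(runif(n_ind, 0, 100), 3)
  })
  # oracle: recursive mean via explicit summation, independent of the
  # package's tapply/mean path
  sub_means <- vapply(subthemes, function(v) sum(v) / length(v), 0)
  oracle <- sum(sub_means) / length(sub_means)
  list(subthemes = subthemes, oracle = oracle)
}

capture_row <- function(farm_id, group, species, count,
                        endemic = FALSE, at_risk = FALSE,
                        introduced = FALSE) {
  tibble::tibble(farm_id = farm_id, taxon_group = group, species = species,
                 count = count, endemic = endemic, at_risk = at_risk,
                 introduced = introduced)
}
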