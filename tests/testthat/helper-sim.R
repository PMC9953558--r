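# Amplitude model with widely separated clusters and no rain, for
# tests that compare classification against simulation truth.
separated_model <- function() amplitude_model(rain_fraction = 0)

# Simulate and quantify one well in one call.
quick_well <- function(copies, seed, epsilon = 0, n_droplets = 20000,
                       model = separated_model()) {
  cfg <- simulation_config(copies = copies, n_droplets = n_droplets,
                           epsilon = epsilon, model = model, seed = seed)
  quantify_well(simulate_well(cfg))
}

# Independent weighted-average quantile oracle: linear interpolation
# at h = (n-1)p + 1 on the sorted values, written without quantile().
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Brute-force tie-aware AUC over all case-control pairs.
oracle_auc <- function(cases, controls) {
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(controls))
}
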