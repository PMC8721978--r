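# Shared fixtures: small, fast simulator settings used across test files.

# Fully deterministic configuration: no sensor noise, no link noise.
noiseless_config <- function(...) {
  cfg <- sim_config(force_noise_sd_bw = 0, acc_noise_sd_g = 0, ...)
  for (pos in c("c7", "l5", "ta")) cfg$acc_link[[pos]][["sigma"]] <- 0
  cfg
}

# A short single-phase protocol (n jumps at 50% HRR) for segmentation tests.
short_protocol <- function(n_jumps = 6, label = "50", fraction = 0.50) {
  session_protocol(labels = label, fractions = fraction, n_jumps = n_jumps)
}

# Per-jump records with known linear structure for regression tests:
# y = b0 + b1*x1 + b2*x2 + noise.
toy_regression <- function(n, b = c(2, 3, -1.5), sd = 1, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- b[1] + b[2] * x1 + b[3] * x2 + rnorm(n, 0, sd)
  list(y = y, X = data.frame(x1 = x1, x2 = x2))
}
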