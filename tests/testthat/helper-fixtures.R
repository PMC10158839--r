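# Shared fixtures for the test suite. All randomness is seeded locally.

# a Causal configuration used throughout: causal (0.72, 0.9, 0.8),
# errors (0.9, 0.8, 0.9) -> data (0.5832, 0.648, 0.576), latent (0.81, 0.8, 0.72)
fix_causal_config <- function() {
  me_config("Causal", rho_xm = 0.9, rho_ym = 0.8,
            err_x = 0.9, err_m = 0.8, err_y = 0.9)
}

# random valid configuration of a given structure, correlations ~ Beta(5, 1.25)
random_config <- function(structure = c("Causal", "Independent", "Reactive")) {
  structure <- match.arg(structure)
  d <- rbeta(5, 5, 1.25)
  switch(structure,
    Causal = me_config("Causal", rho_xm = d[1], rho_ym = d[2],
                       err_x = d[3], err_m = d[4], err_y = d[5]),
    Independent = me_config("Independent", rho_xm = d[1], rho_xy = d[2],
                            err_x = d[3], err_m = d[4], err_y = d[5]),
    Reactive = me_config("Reactive", rho_xy = d[1], rho_ym = d[2],
                         err_x = d[3], err_m = d[4], err_y = d[5]))
}

# standard-error of a sample correlation (used for Monte-Carlo tolerance)
cor_se <- function(rho, n) (1 - rho^2) / sqrt(n)

triple_vec <- function(x) unname(as.numeric(x))
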