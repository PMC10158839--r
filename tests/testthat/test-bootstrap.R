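# Bootstrap regions for data correlations, HDI computation, and the
# configuration-library filter.

test_that("hdi finds the shortest mass-covering interval", {
  set.seed(61)
  u <- runif(10000)
  iv <- hdi(u, 0.95)
  expect_lt(abs(diff(iv) - 0.95), 0.02)

  expect_equal(unname(hdi(rep(3.5, 50))), c(3.5, 3.5))
  expect_error(hdi(1:10), "at least 20")

  # right-skewed Beta(5, 1.25): 95% HDI hugs the upper boundary near (0.5, 1)
  b <- rbeta(100000, 5, 1.25)
  ivb <- hdi(b, 0.95)
  expect_lt(abs(ivb[1] - 0.5), 0.03)
  expect_gt(ivb[2], 0.97)
})

test_that("null triplets give bootstrap regions covering zero", {
  set.seed(62)
  d <- data.frame(x = rnorm(1000), m = rnorm(1000), y = rnorm(1000))
  boot <- bootstrap_correlations(triplet_data(d), n_boot = 400, seed = 1)
  expect_true(all(boot$region[, "lo"] < 0 & boot$region[, "hi"] > 0))
  # the point estimate lies inside the region
  pt <- as.numeric(boot$point)[c("rho_xm", "rho_xy", "rho_ym")]
  expect_true(all(pt >= boot$region[, "lo"] & pt <= boot$region[, "hi"]))
})

test_that("bootstrap regions cover the implied data correlations", {
  cfg <- fix_causal_config()
  truth <- as.numeric(implied_data_cor(cfg))[c("rho_xm", "rho_xy", "rho_ym")]
  joint <- 0; marginal <- 0
  for (i in 1:50) {
    d <- simulate_triplet(cfg, 5000, seed = 300 + i)
    boot <- bootstrap_correlations(d, n_boot = 1000, seed = i)
    ok <- truth >= boot$region[, "lo"] & truth <= boot$region[, "hi"]
    joint <- joint + all(ok)
    marginal <- marginal + mean(ok)
  }
  # each 95% interval covers its correlation ~95% of the time; requiring all
  # three at once costs a few points (the resampled correlations are strongly
  # dependent), so the joint rate sits near 90% and the bound below leaves
  # room for binomial noise at 50 repetitions
  expect_gte(marginal / 50, 0.9)
  expect_gte(joint / 50, 0.84)
})

test_that("multistate bootstrap uses the canonical correlation identity", {
  cfg <- me_config("Causal", rho_xm = 0.9, rho_ym = 0.8)
  d <- simulate_triplet(cfg, 400, seed = 63, x_kind = "multistate")
  est <- estimate_data_cors(d)
  xb <- as.matrix(d[paste0("x", 1:8)])
  fit <- stats::lm.fit(cbind(1, xb[, -1]), d$m)
  r2 <- 1 - sum(fit$residuals^2) / sum((d$m - mean(d$m))^2)
  expect_equal(est$rho_xm, sqrt(r2), tolerance = 1e-10)
  boot <- bootstrap_correlations(d, n_boot = 100, seed = 2)
  expect_true(all(boot$samples[, "r_xm"] >= 0))
})

test_that("degenerate resamples abort after the redraw budget", {
  d <- data.frame(x = rnorm(50), m = rep(1, 50), y = rnorm(50))
  d$m <- 1  # mediator has no variance: every resample is degenerate
  expect_error(bootstrap_correlations(triplet_data(d), n_boot = 100, seed = 3),
               "degenerate")
})

test_that("covariate effects are residualized out before correlating", {
  set.seed(64)
  n <- 2000
  sex <- rep(c(0, 5), n / 2)
  d <- data.frame(x = rnorm(n), m = rnorm(n) + sex, y = rnorm(n) + sex,
                  sex = sex)
  boot <- bootstrap_correlations(triplet_data(d, covariates = "sex"),
                                 n_boot = 150, seed = 4)
  # without residualization r_ym would be ~0.86; with it, near zero
  expect_lt(abs(boot$point$rho_ym), 0.1)
})

test_that("the vacuous region keeps every configuration, shrinking only removes", {
  lib <- config_library("Causal", n_configs = 400, sample_size = 200, seed = 65)
  fake_region <- function(reg) {
    structure(list(region = reg, samples = NULL), class = "boot_cors")
  }
  all_reg <- matrix(c(-1, -1, -1, 1, 1, 1), 3,
                    dimnames = list(c("r_xm", "r_xy", "r_ym"), c("lo", "hi")))
  fs_all <- filter_configs(lib, fake_region(all_reg))
  expect_equal(fs_all$n_survivors, 400)

  tight <- all_reg; tight[, "lo"] <- 0.4; tight[, "hi"] <- 0.8
  fs_tight <- filter_configs(lib, fake_region(tight))
  expect_lte(fs_tight$n_survivors, fs_all$n_survivors)
  tighter <- tight; tighter[, "lo"] <- 0.55; tighter[, "hi"] <- 0.7
  fs_tighter <- filter_configs(lib, fake_region(tighter))
  expect_lte(fs_tighter$n_survivors, fs_tight$n_survivors)
  # survivors of the tighter region are a subset of the tight region's
  expect_true(all(rownames(fs_tighter$survivors) %in%
                  rownames(fs_tight$survivors)))

  off <- all_reg; off[, "lo"] <- 0.998; off[, "hi"] <- 0.999
  fs_none <- filter_configs(lib, fake_region(off))
  expect_equal(fs_none$n_survivors, 0)
  expect_null(fs_none$summaries)
  df <- as.data.frame(fs_none)
  expect_equal(df$n_survivors, 0)
})

test_that("closed-loop filtering recovers the generating parameters", {
  lib <- config_library("Causal", n_configs = 8000, sample_size = 200,
                        seed = 66)
  hits <- 0
  set.seed(67)
  for (run in 1:10) {
    truth <- random_config("Causal")
    d <- simulate_triplet(truth, 200, seed = 900 + run)
    boot <- bootstrap_correlations(d, n_boot = 300, seed = run)
    fs <- filter_configs(lib, boot)
    if (fs$n_survivors < 20) next
    lat <- latent_from_config(truth)
    s <- fs$summaries
    inside <- function(p, v) {
      v >= s$lo[s$parameter == p] & v <= s$hi[s$parameter == p]
    }
    ok <- inside("rho_xu", lat$rho_xu) & inside("rho_mu", lat$rho_mu) &
      inside("rho_yu", lat$rho_yu)
    hits <- hits + ok
  }
  expect_gte(hits, 8)
})

test_that("a near-unit genotype-mediator correlation forces a strong causal edge", {
  # if the region pins |r_xm| near 1, surviving Causal configs must have
  # err_x * rho_xm near 1 and hence rho_xm near 1
  lib <- config_library("Causal", n_configs = 8000, sample_size = 500,
                        seed = 68)
  reg <- matrix(c(0.93, -1, -1, 1, 1, 1), 3,
                dimnames = list(c("r_xm", "r_xy", "r_ym"), c("lo", "hi")))
  fs <- filter_configs(lib,
                       structure(list(region = reg), class = "boot_cors"))
  expect_gt(fs$n_survivors, 0)
  expect_gt(min(fs$survivors$rho_xm), 0.9)
})
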