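# Bayesian model selection: enumeration, marginal likelihoods, posterior
# behavior, the weakest-correlation rule, and the vectorized fast path.

# construct a dataset whose *sample* correlation matrix equals R exactly:
# orthonormalize residualized noise, then impose chol(R)
exact_cor_data <- function(n, R, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * 3), n, 3)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))
  D <- Q %*% chol(R) * sqrt(n - 1)
  data.frame(x = D[, 1], m = D[, 2], y = D[, 3])
}

test_that("model enumeration matches the option sets and label partition", {
  m3 <- mediation_models("three_choice")
  expect_identical(m3$label, c("Causal", "Independent", "Reactive"))

  me <- mediation_models("expanded")
  expect_equal(nrow(me), 10)
  expect_identical(sort(unique(me$label)),
                   c("Causal", "Complex", "Independent", "Other", "Reactive"))
  expect_equal(sum(me$label == "Other"), 6)
  # no model contains both directions of the M-Y edge
  for (e in me$edges) expect_false(all(c("b", "b_rev") %in% e))
  # the excluded reversed duplicates are really absent
  expect_false(any(vapply(me$edges, identical, TRUE, y = "b_rev")))
  expect_false(any(vapply(me$edges, setequal, TRUE, y = c("a", "c", "b_rev"))))
})

test_that("single reversed edge is exactly likelihood-equivalent to its forward twin", {
  set.seed(31)
  for (i in 1:100) {
    cfg <- random_config(sample(c("Causal", "Independent", "Reactive"), 1))
    d <- simulate_triplet(cfg, 120, seed = i)
    expect_equal(log_marginal_likelihood(d, "b"),
                 log_marginal_likelihood(d, "b_rev"), tolerance = 1e-8)
  }
})

test_that("the reversed triangle tracks the Complex model (Markov equivalence)", {
  # the fully connected DAGs are Markov equivalent; under per-node conjugate
  # priors their marginal likelihoods agree asymptotically, not identically
  set.seed(32)
  diffs200 <- diffs2000 <- numeric(20)
  for (i in 1:20) {
    cfg <- random_config("Causal")
    d200 <- simulate_triplet(cfg, 200, seed = i)
    d2000 <- simulate_triplet(cfg, 2000, seed = 1000 + i)
    diffs200[i] <- log_marginal_likelihood(d200, c("a", "c", "b_rev")) -
      log_marginal_likelihood(d200, "a+b+c")
    diffs2000[i] <- log_marginal_likelihood(d2000, c("a", "c", "b_rev")) -
      log_marginal_likelihood(d2000, "a+b+c")
  }
  expect_lt(max(abs(diffs200)), 1)
  expect_lt(max(abs(diffs2000)), 1)
})

test_that("null data prefer the empty model and penalize irrelevant edges", {
  set.seed(33)
  n <- 200
  wins <- 0
  bf_extra <- numeric(300)
  for (i in 1:300) {
    d <- data.frame(x = rnorm(n), m = rnorm(n), y = rnorm(n))
    l_none <- log_marginal_likelihood(d, "none")
    l_causal <- log_marginal_likelihood(d, "a+b")
    wins <- wins + (l_none > l_causal)
    # log Bayes factor for adding the spurious edge a to the empty model
    bf_extra[i] <- log_marginal_likelihood(d, "a") - l_none
  }
  expect_gte(wins / 300, 0.95)
  expect_lt(mean(bf_extra), 0)
})

test_that("selection is invariant to the measurement scale of M and Y", {
  set.seed(34)
  for (i in 1:100) {
    cfg <- random_config(sample(c("Causal", "Independent", "Reactive"), 1))
    d <- simulate_triplet(cfg, 150, seed = i)
    d10 <- as.data.frame(d)
    d10$m <- 10 * d10$m
    d10$y <- 10 * d10$y
    for (opt in c("three_choice", "expanded")) {
      expect_identical(triplet_bms(d, opt)$selected,
                       triplet_bms(d10, opt)$selected)
    }
  }
})

test_that("posteriors normalize and flag exact ties on symmetric data", {
  R <- matrix(0.6, 3, 3); diag(R) <- 1
  d <- exact_cor_data(400, R, seed = 5)
  fit <- triplet_bms(d, "three_choice")
  expect_equal(sum(fit$posterior), 1)
  # r_xm = r_xy = r_ym exactly: the three models have equal marginal
  # likelihood and the posterior is uniform
  expect_equal(unname(fit$posterior), rep(1 / 3, 3), tolerance = 1e-9)
  expect_true(fit$tie)
})

test_that("strong error-free Causal data are selected with high posterior", {
  cfg <- me_config("Causal", rho_xm = 0.9, rho_ym = 0.8)
  d <- simulate_triplet(cfg, 5000, seed = 35)
  fit <- triplet_bms(d, "three_choice")
  expect_identical(fit$selected, "Causal")
  expect_gt(fit$posterior[["a+b"]], 0.95)
})

test_that("middle-variable error drives expanded selection toward Complex", {
  cfg <- me_config("Causal", rho_xm = 0.9, rho_ym = 0.8, err_m = 0.8)
  sel <- character(200)
  for (i in 1:200) {
    d <- simulate_triplet(cfg, 5000, seed = 7000 + i)
    est <- estimate_data_cors(d)
    sel[i] <- classify_cors(est$rho_xm, est$rho_xy, est$rho_ym, 5000,
                            "expanded")
  }
  expect_gt(mean(sel == "Complex"), 0.5)
})

test_that("the weakest-correlation rule reads the weakest pair", {
  expect_identical(weakest_correlation_rule(c(0.5, 0.8, 0.7)), "Causal")
  expect_identical(weakest_correlation_rule(c(0.8, 0.7, 0.5)), "Independent")
  expect_identical(weakest_correlation_rule(c(0.7, 0.5, 0.8)), "Reactive")
  expect_identical(weakest_correlation_rule(c(0.5, 0.5, 0.8)), "ambiguous")
  dm <- simulate_triplet(fix_causal_config(), 100, seed = 1,
                         x_kind = "multistate")
  expect_error(weakest_correlation_rule(dm), "not applicable")
})

test_that("three-choice Bayesian selection implements the weakest-correlation rule", {
  set.seed(36)
  agree <- 0; tot <- 0
  for (st in c("Causal", "Independent", "Reactive")) {
    for (i in 1:700) {
      cfg <- random_config(st)
      d <- simulate_triplet(cfg, 200, seed = 10000 + tot)
      est <- estimate_data_cors(d)
      rule <- weakest_correlation_rule(est)
      if (rule == "ambiguous") next
      sel <- classify_cors(est$rho_xm, est$rho_xy, est$rho_ym, 200,
                           "three_choice")
      tot <- tot + 1
      agree <- agree + (sel == rule)
    }
  }
  expect_gte(agree / tot, 0.99)
})

test_that("the vectorized fast path agrees with the full fit", {
  set.seed(37)
  for (i in 1:40) {
    cfg <- random_config(sample(c("Causal", "Independent", "Reactive"), 1))
    d <- simulate_triplet(cfg, 150, seed = i)
    est <- estimate_data_cors(d)
    for (opt in c("three_choice", "expanded")) {
      expect_identical(
        classify_cors(est$rho_xm, est$rho_xy, est$rho_ym, 150, opt),
        triplet_bms(d, opt)$selected)
    }
  }
})

test_that("covariates are absorbed with flat priors and bad designs error", {
  cfg <- fix_causal_config()
  d <- as.data.frame(simulate_triplet(cfg, 300, seed = 38))
  d$sex <- rep(c(0, 1), 150)
  d$m <- d$m + 0.8 * d$sex
  dt <- triplet_data(d, covariates = "sex")
  fit <- triplet_bms(dt, "expanded")
  expect_s3_class(fit, "triplet_bms")
  expect_equal(sum(fit$posterior), 1)

  d$dup <- d$sex
  expect_error(triplet_bms(triplet_data(d, covariates = c("sex", "dup"))),
               "design error")
})

test_that("multistate genotypes enter as a dosage block", {
  cfg <- me_config("Causal", rho_xm = 0.9, rho_ym = 0.85)
  d <- simulate_triplet(cfg, 1500, seed = 39, x_kind = "multistate")
  fit <- triplet_bms(d, "three_choice")
  expect_identical(fit$selected, "Causal")
  lml <- log_marginal_likelihood(d, "a+b")
  expect_true(is.finite(lml))
})
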