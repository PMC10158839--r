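# Bayesian model selection over mediation DAGs. The joint marginal likelihood
# of a triplet factorizes as p(M | parents) * p(Y | parents); each factor is
# the closed-form marginal likelihood of a Gaussian linear model under a
# conjugate prior: effect prior variance phi2 * sigma^2 per standardized
# predictor, inverse-gamma(kappa/2, lambda/2) on sigma^2, flat priors on the
# intercept and covariates.

#' Prior settings for Bayesian model selection
#'
#' `phi2` is the prior variance (in units of the residual variance) of each
#' edge effect on standardized predictors — the main knob affecting how often
#' the expanded option set prefers richer models. `kappa` and `lambda` are the
#' inverse-gamma shape/rate hyperparameters of the residual variance; the
#' defaults are weakly informative. Responses and predictors are standardized
#' before likelihood evaluation, making selection invariant to the scale of
#' the inputs.
#'
#' @param phi2 Effect-size prior variance, positive. Default 1.
#' @param kappa,lambda Inverse-gamma hyperparameters, positive. Default 0.001.
#' @return Object of class `"bms_priors"`.
#' @export
bms_priors <- function(phi2 = 1, kappa = 0.001, lambda = 0.001) {
  stopifnot(phi2 > 0, kappa > 0, lambda > 0)
  structure(list(phi2 = phi2, kappa = kappa, lambda = lambda),
            class = "bms_priors")
}

#' Enumerate mediation models
#'
#' The three-choice option set holds exactly the Causal (`a, b`), Independent
#' (`a, c`), and Reactive (`c, b_rev`) models. The expanded set enumerates all
#' acyclic edge subsets over `a` (X->M), `b` (M->Y), `c` (X->Y), and `b_rev`
#' (Y->M), minus reversed-edge models that are likelihood-equivalent to a
#' retained M->Y counterpart (`b_rev` alone duplicates `b`; the fully
#' connected `a, c, b_rev` duplicates the Complex model `a, b, c`). Edge
#' subsets other than the four named models are labelled `"Other"`
#' (nonmediation).
#'
#' @param option_set `"three_choice"` or `"expanded"`.
#' @return Data frame with columns `model` (id), `label`, and list-column
#'   `edges`.
#' @export
mediation_models <- function(option_set = c("three_choice", "expanded")) {
  option_set <- match.arg(option_set)
  all_models <- list(
    "a+b"     = c("a", "b"),
    "a+c"     = c("a", "c"),
    "c+b_rev" = c("c", "b_rev"),
    "a+b+c"   = c("a", "b", "c"),
    "none"    = character(0),
    "a"       = "a",
    "b"       = "b",
    "c"       = "c",
    "b+c"     = c("b", "c"),
    "a+b_rev" = c("a", "b_rev"))
  ids <- if (option_set == "three_choice") c("a+b", "a+c", "c+b_rev")
         else names(all_models)
  labels <- vapply(ids, function(id) .model_label(all_models[[id]]), "")
  out <- data.frame(model = ids, label = labels, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$edges <- unname(all_models[ids])
  out
}

.model_label <- function(edges) {
  e <- sort(edges)
  if (identical(e, c("a", "b"))) "Causal"
  else if (identical(e, c("a", "c"))) "Independent"
  else if (identical(e, c("b_rev", "c"))) "Reactive"
  else if (identical(e, c("a", "b", "c"))) "Complex"
  else "Other"
}

.std <- function(v) {
  s <- stats::sd(v)
  if (s == 0) stop("cannot standardize a constant column")
  (v - mean(v)) / s
}

# Closed-form log marginal likelihood of y ~ F alpha + W beta with flat
# prior on alpha, beta ~ N(0, phi2 sigma^2 I) and sigma^2 ~ IG(kappa/2,
# lambda/2). y and W standardized by the caller; F carries the intercept and
# any covariates.
.logml_factor <- function(y, W, F, priors) {
  n <- length(y)
  q <- ncol(F)
  if (is.null(W) || ncol(W) == 0) {
    ldV <- 0
    Vi_y <- y
    Vi_F <- F
  } else {
    p <- ncol(W)
    A <- crossprod(W) + diag(1 / priors$phi2, p)
    ch <- chol(A)
    ldV <- p * log(priors$phi2) + 2 * sum(log(diag(ch)))
    WtY <- crossprod(W, y)
    WtF <- crossprod(W, F)
    Vi_y <- y - W %*% backsolve(ch, forwardsolve(t(ch), WtY))
    Vi_F <- F - W %*% backsolve(ch, forwardsolve(t(ch), WtF))
  }
  FVF <- crossprod(F, Vi_F)
  FVy <- crossprod(F, Vi_y)
  S <- drop(sum(y * Vi_y) - t(FVy) %*% solve(FVF, FVy))
  ldF <- as.numeric(determinant(FVF, logarithm = TRUE)$modulus)
  -((n - q) / 2) * log(2 * pi) - 0.5 * ldV - 0.5 * ldF +
    (priors$kappa / 2) * log(priors$lambda / 2) - lgamma(priors$kappa / 2) +
    lgamma((n - q + priors$kappa) / 2) -
    ((n - q + priors$kappa) / 2) * log((S + priors$lambda) / 2)
}

# Extract standardized design blocks from a triplet dataset.
.design_blocks <- function(data) {
  stopifnot(is.data.frame(data))
  if (!inherits(data, "triplet_data")) data <- triplet_data(data)
  x_cols <- attr(data, "x_cols")
  covs <- attr(data, "covariate_cols")
  n <- nrow(data)
  m <- .std(data[[attr(data, "m_col")]])
  y <- .std(data[[attr(data, "y_col")]])
  Xb <- as.matrix(data[x_cols])
  Xb <- scale(Xb)
  keep <- apply(is.finite(Xb), 2, all)   # constant dosage columns drop out
  Xb <- Xb[, keep, drop = FALSE]
  if (ncol(Xb) == 0) stop("design error: genotype block is constant")
  F <- cbind(`(Intercept)` = rep(1, n))
  if (length(covs)) F <- cbind(F, as.matrix(data[covs]))
  if (qr(F)$rank < ncol(F)) stop("design error: covariate block is rank deficient")
  multistate <- attr(data, "x_kind") == "multistate"
  # centered one-hot dosage columns sum to zero across the block: that single
  # redundancy is expected; anything beyond it is a design error
  slack <- if (multistate && ncol(Xb) > 1) 1L else 0L
  full <- cbind(F, Xb, m, y)
  if (qr(full)$rank < ncol(full) - slack) {
    stop("design error: rank-deficient design beyond the dosage-block redundancy")
  }
  list(m = m, y = y, X = Xb, F = F, n = n, multistate = multistate)
}

# The eight distinct regression factors any mediation model is assembled from.
.all_factors <- function(blocks, priors) {
  with(blocks, list(
    m0  = .logml_factor(m, NULL, F, priors),
    mX  = .logml_factor(m, X, F, priors),
    mY  = .logml_factor(m, cbind(y), F, priors),
    mXY = .logml_factor(m, cbind(X, y), F, priors),
    y0  = .logml_factor(y, NULL, F, priors),
    yX  = .logml_factor(y, X, F, priors),
    yM  = .logml_factor(y, cbind(m), F, priors),
    yXM = .logml_factor(y, cbind(X, m), F, priors)))
}

.model_logml <- function(edges, fac) {
  mkey <- paste0("m", if ("a" %in% edges && "b_rev" %in% edges) "XY"
                      else if ("a" %in% edges) "X"
                      else if ("b_rev" %in% edges) "Y" else "0")
  ykey <- paste0("y", if ("c" %in% edges && "b" %in% edges) "XM"
                      else if ("c" %in% edges) "X"
                      else if ("b" %in% edges) "M" else "0")
  fac[[mkey]] + fac[[ykey]]
}

#' Log marginal likelihood of one mediation model
#'
#' Evaluates the closed-form joint marginal density of a triplet dataset under
#' a single mediation model, factorized as (density of M given its parents)
#' times (density of Y given its parents). Responses and predictors are
#' standardized first; a multistate genotype enters as its centered dosage
#' block; covariates receive flat priors identically across models, so Bayes
#' factors compare edge structure only. Deterministic. The value refers to the
#' standardized data — the standardization Jacobian is constant across models.
#'
#' @param data A [triplet_data()] (or plain data frame with columns `x`, `m`,
#'   `y`).
#' @param model Model id from [mediation_models()] (e.g. `"a+b"`) or a
#'   character vector of edges among `a`, `b`, `c`, `b_rev`.
#' @param priors A [bms_priors()].
#' @return Log marginal likelihood (numeric scalar).
#' @export
log_marginal_likelihood <- function(data, model, priors = bms_priors()) {
  edges <- .resolve_edges(model)
  blocks <- .design_blocks(data)
  .model_logml(edges, .all_factors(blocks, priors))
}

.resolve_edges <- function(model) {
  if (length(model) == 1 && grepl("[+]|^none$", model)) {
    edges <- setdiff(strsplit(model, "+", fixed = TRUE)[[1]], "none")
  } else {
    edges <- model
  }
  bad <- setdiff(edges, c("a", "b", "c", "b_rev"))
  if (length(bad)) stop("unknown edges: ", paste(bad, collapse = ", "))
  if (all(c("b", "b_rev") %in% edges)) stop("cyclic model: b and b_rev")
  edges
}

#' Bayesian model selection for a triplet
#'
#' Fits every model in the chosen option set by closed-form marginal
#' likelihood, normalizes posterior probabilities under a uniform model prior,
#' and selects the maximum-posterior model. With the expanded set, a dataset
#' whose best model is neither Causal, Independent, Reactive, nor Complex is
#' classified `"Other"` (nonmediation).
#'
#' @param data A [triplet_data()] or plain data frame with columns `x` (or
#'   `x1..xk`), `m`, `y`, and optional covariates declared via
#'   [triplet_data()].
#' @param options `"three_choice"` or `"expanded"`.
#' @param priors A [bms_priors()].
#' @return Object of class `"triplet_bms"`: log marginal likelihoods and
#'   posterior probabilities per model, the selected model id and label, the
#'   estimated data correlations, and a tie flag (posterior gap below 1e-12,
#'   resolved by enumeration order).
#' @examples
#' cfg <- me_config("Causal", rho_xm = 0.9, rho_ym = 0.8)
#' dat <- simulate_triplet(cfg, n = 500, seed = 11)
#' fit <- triplet_bms(dat, options = "three_choice")
#' fit
#' @export
triplet_bms <- function(data, options = c("three_choice", "expanded"),
                        priors = bms_priors()) {
  options <- match.arg(options)
  if (!inherits(data, "triplet_data")) data <- triplet_data(data)
  models <- mediation_models(options)
  blocks <- .design_blocks(data)
  fac <- .all_factors(blocks, priors)
  lml <- vapply(models$edges, .model_logml, 0, fac = fac)
  names(lml) <- models$model
  post <- exp(lml - max(lml))
  post <- post / sum(post)
  best <- which.max(post)
  sp <- sort(post, decreasing = TRUE)
  tie <- length(sp) > 1 && (sp[1] - sp[2]) < 1e-12
  structure(list(
    log_marginal = lml, posterior = post, models = models,
    selected_model = models$model[best], selected = models$label[best],
    option_set = options, n = blocks$n, priors = priors, tie = tie,
    data_cors = estimate_data_cors(data)),
    class = "triplet_bms")
}

#' @export
print.triplet_bms <- function(x, ...) {
  cat(sprintf("Bayesian mediation model selection (%s options, N=%d)\n",
              x$option_set, x$n))
  cat(sprintf("Selected: %s (model %s, posterior %.3f)%s\n\n",
              x$selected, x$selected_model, x$posterior[x$selected_model],
              if (x$tie) " [tie]" else ""))
  tab <- data.frame(label = x$models$label,
                    log_marginal = round(x$log_marginal, 3),
                    posterior = round(x$posterior, 4))
  print(tab)
  invisible(x)
}

#' @export
summary.triplet_bms <- function(object, ...) {
  r <- object$data_cors
  cat(sprintf("Estimated data correlations: r_xm=%.3f r_xy=%.3f r_ym=%.3f\n",
              r$rho_xm, r$rho_xy, r$rho_ym))
  lat <- tryCatch(estimate_latent(r), error = function(e) NULL)
  if (!is.null(lat)) {
    cat(sprintf("Estimated latent correlations: r_xu=%.3f r_mu=%.3f r_yu=%.3f%s\n",
                lat$rho_xu, lat$rho_mu, lat$rho_yu,
                if (lat$heywood) " [Heywood: clipped]" else ""))
  }
  print(object)
  invisible(object)
}

#' @export
plot.triplet_bms <- function(x, ...) {
  graphics::barplot(x$posterior, names.arg = x$models$label, las = 2,
                    ylab = "posterior probability",
                    main = sprintf("Model posteriors (%s)", x$option_set), ...)
  invisible(x)
}

#' Estimated data correlations of a triplet dataset
#'
#' Pearson correlations among the measured variables; when the genotype is a
#' multistate dosage block, its correlations with M and Y are first canonical
#' correlations, computed as the square root of the regression R-squared
#' (identical for a univariate response, and nonnegative by construction).
#' Covariates, if declared, are residualized out of M and Y first.
#'
#' @param data A [triplet_data()].
#' @return A `corr_triple` with role `"estimated"`.
#' @export
estimate_data_cors <- function(data) {
  if (!inherits(data, "triplet_data")) data <- triplet_data(data)
  m <- data[[attr(data, "m_col")]]
  y <- data[[attr(data, "y_col")]]
  covs <- attr(data, "covariate_cols")
  if (length(covs)) {
    C <- as.matrix(data[covs])
    m <- stats::lm.fit(cbind(1, C), m)$residuals
    y <- stats::lm.fit(cbind(1, C), y)$residuals
  }
  if (attr(data, "x_kind") == "multistate") {
    Xb <- as.matrix(data[attr(data, "x_cols")])
    rxm <- .canon_cor(Xb, m)
    rxy <- .canon_cor(Xb, y)
  } else {
    x <- data[[attr(data, "x_cols")]]
    if (length(covs)) x <- stats::lm.fit(cbind(1, C), x)$residuals
    rxm <- stats::cor(x, m)
    rxy <- stats::cor(x, y)
  }
  corr_triple(rho_xy = rxy, rho_xm = rxm, rho_ym = stats::cor(y, m),
              role = "estimated")
}

# first canonical correlation of a column block with a univariate response:
# sqrt of the R^2 of the regression of the response on the block
.canon_cor <- function(X, y) {
  fit <- stats::lm.fit(cbind(1, X), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  sqrt(max(0, r2))
}

#' Weakest-correlation decision rule
#'
#' Deterministic counterpart of three-choice Bayesian selection for univariate
#' triplets: select the structure with no direct edge between the pair whose
#' estimated data correlation is weakest in magnitude — Causal when `|r_xy|`
#' is strictly weakest, Independent when `|r_ym|`, Reactive when `|r_xm|`.
#' The rule holds only for univariate X, M, and Y.
#'
#' @param x A `corr_triple` (data or estimated), a numeric vector
#'   `c(rho_xy, rho_xm, rho_ym)`, or a univariate [triplet_data()].
#' @return `"Causal"`, `"Independent"`, `"Reactive"`, or `"ambiguous"` on a
#'   tie for the weakest magnitude.
#' @export
weakest_correlation_rule <- function(x) {
  if (inherits(x, "triplet_data")) {
    if (attr(x, "x_kind") == "multistate") {
      stop("rule not applicable: the weakest-correlation rule holds only for univariate X")
    }
    x <- estimate_data_cors(x)
  }
  v <- abs(.triple_values(x))
  if (sum(v == min(v)) > 1) return("ambiguous")
  c("Causal", "Reactive", "Independent")[which.min(v)]
}

#' Vectorized classification from sample correlations
#'
#' Fast path for simulation studies with univariate Gaussian variables: the
#' marginal likelihoods of all mediation models depend on the data only
#' through the three sample correlations and the sample size, so whole
#' batches of datasets can be classified from their correlation vectors.
#' Agrees exactly with [triplet_bms()] on the same data.
#'
#' @param r_xm,r_xy,r_ym Equal-length vectors of sample correlations.
#' @param n Sample size of each dataset (scalar).
#' @param options `"three_choice"` or `"expanded"`.
#' @param priors A [bms_priors()].
#' @return Character vector of selected labels (`"Causal"`, `"Independent"`,
#'   `"Reactive"`, and for the expanded set also `"Complex"` and `"Other"`).
#' @export
classify_cors <- function(r_xm, r_xy, r_ym, n,
                          options = c("three_choice", "expanded"),
                          priors = bms_priors()) {
  options <- match.arg(options)
  stopifnot(length(r_xm) == length(r_xy), length(r_xy) == length(r_ym),
            length(n) == 1, n >= 10)
  phi2 <- priors$phi2; kappa <- priors$kappa; lambda <- priors$lambda
  t1 <- n - 1
  const <- -(t1 / 2) * log(2 * pi) - 0.5 * log(n) +
    (kappa / 2) * log(lambda / 2) - lgamma(kappa / 2) +
    lgamma((t1 + kappa) / 2)
  half <- (t1 + kappa) / 2
  c1 <- t1 / (t1 + 1 / phi2)
  f0 <- const - half * log((t1 + lambda) / 2)
  f1 <- function(r) {
    S <- t1 * (1 - c1 * r^2)
    const - 0.5 * log1p(phi2 * t1) - half * log((S + lambda) / 2)
  }
  f2 <- function(r1, r2, r12) {
    a11 <- t1 + 1 / phi2; a12 <- t1 * r12
    det <- a11^2 - a12^2
    S <- t1 - t1^2 * (a11 * (r1^2 + r2^2) - 2 * a12 * r1 * r2) / det
    ldV <- log((1 + phi2 * t1)^2 - (phi2 * t1 * r12)^2)
    const - 0.5 * ldV - half * log((S + lambda) / 2)
  }
  mX <- f1(r_xm); mY <- f1(r_ym); yX <- f1(r_xy); yM <- f1(r_ym)
  if (options == "three_choice") {
    lml <- cbind(Causal = mX + yM, Independent = mX + yX, Reactive = mY + yX)
    labels <- colnames(lml)
  } else {
    mXY <- f2(r_xm, r_ym, r_xy)
    yXM <- f2(r_xy, r_ym, r_xm)
    models <- mediation_models("expanded")
    lml <- cbind(mX + yM,            # a+b      Causal
                 mX + yX,            # a+c      Independent
                 mY + yX,            # c+b_rev  Reactive
                 mX + yXM,           # a+b+c    Complex
                 f0 + f0,            # none
                 mX + f0,            # a
                 f0 + yM,            # b
                 f0 + yX,            # c
                 f0 + yXM,           # b+c
                 mXY + f0)           # a+b_rev
    labels <- models$label
  }
  labels[max.col(lml, ties.method = "first")]
}
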