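# Case-study diagnostics: bootstrap the observed triplet to get an empirical
# region for its data correlations, then filter a library of simulated
# configurations to those whose realized correlations fall jointly inside the
# region, and summarize the feasible causal / error / latent parameters.

#' Bootstrap distribution of the data correlations
#'
#' Case resampling: rows are drawn with replacement `n_boot` times and the
#' three data correlations are re-estimated for each resample (first canonical
#' correlation against a multistate genotype block, Pearson otherwise;
#' covariates are residualized out of M and Y beforehand). Degenerate
#' resamples (a zero-variance column) are redrawn and counted; more than 1%
#' redraws aborts. The region is the central interval of each correlation's
#' bootstrap distribution at the requested level (or the full min/max range,
#' which is noisier and grows with `n_boot`).
#'
#' @param data A [triplet_data()] with at least 30 rows.
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param seed Optional seed.
#' @param level Coverage of the central region (default 0.95).
#' @param region `"central"` or `"minmax"`.
#' @return Object of class `"boot_cors"`: `samples` (`n_boot` x 3 matrix of
#'   `r_xm`, `r_xy`, `r_ym`), `point` (the full-sample estimate), `region`
#'   (3 x 2 matrix of interval bounds), and the redraw counter.
#' @export
bootstrap_correlations <- function(data, n_boot = 10000, seed = NULL,
                                   level = 0.95,
                                   region = c("central", "minmax")) {
  region <- match.arg(region)
  if (!inherits(data, "triplet_data")) data <- triplet_data(data)
  stopifnot(nrow(data) >= 30, n_boot >= 100)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  covs <- attr(data, "covariate_cols")
  m <- data[[attr(data, "m_col")]]
  y <- data[[attr(data, "y_col")]]
  multistate <- attr(data, "x_kind") == "multistate"
  if (multistate) {
    X <- as.matrix(data[attr(data, "x_cols")])
  } else {
    X <- data[[attr(data, "x_cols")]]
  }
  if (length(covs)) {
    C <- cbind(1, as.matrix(data[covs]))
    m <- stats::lm.fit(C, m)$residuals
    y <- stats::lm.fit(C, y)$residuals
  }
  one_sample <- function(idx) {
    mm <- m[idx]; yy <- y[idx]
    if (stats::sd(mm) == 0 || stats::sd(yy) == 0) return(NULL)
    if (multistate) {
      Xb <- X[idx, , drop = FALSE]
      keep <- apply(Xb, 2, function(col) stats::sd(col) > 0)
      if (sum(keep) < 1) return(NULL)
      Xb <- Xb[, keep, drop = FALSE]
      c(.canon_cor(Xb, mm), .canon_cor(Xb, yy), stats::cor(yy, mm))
    } else {
      xx <- X[idx]
      if (stats::sd(xx) == 0) return(NULL)
      c(stats::cor(xx, mm), stats::cor(xx, yy), stats::cor(yy, mm))
    }
  }
  samples <- matrix(NA_real_, n_boot, 3,
                    dimnames = list(NULL, c("r_xm", "r_xy", "r_ym")))
  redraws <- 0L
  max_redraws <- ceiling(0.01 * n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      val <- one_sample(sample.int(n, n, replace = TRUE))
      if (!is.null(val)) break
      redraws <- redraws + 1L
      if (redraws > max_redraws) {
        stop("more than 1% of bootstrap resamples were degenerate; aborting")
      }
    }
    samples[b, ] <- val
  }
  point <- one_sample(seq_len(n))
  reg <- if (region == "central") {
    a <- (1 - level) / 2
    t(apply(samples, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  } else {
    t(apply(samples, 2, range))
  }
  colnames(reg) <- c("lo", "hi")
  structure(list(samples = samples,
                 point = corr_triple(rho_xy = point[2], rho_xm = point[1],
                                     rho_ym = point[3], role = "estimated"),
                 region = reg, n_boot = n_boot, level = level,
                 region_type = region, n_redraws = redraws),
            class = "boot_cors")
}

#' @export
print.boot_cors <- function(x, ...) {
  cat(sprintf("<boot_cors> %d resamples, %s %.0f%% region (%d redraws)\n",
              x$n_boot, x$region_type, 100 * x$level, x$n_redraws))
  est <- as.numeric(x$point)[c("rho_xm", "rho_xy", "rho_ym")]
  tab <- cbind(estimate = est, x$region)
  rownames(tab) <- c("r_xm", "r_xy", "r_ym")
  print(round(tab, 3))
  invisible(x)
}

#' Highest density interval of empirical samples
#'
#' Shortest contiguous interval containing the requested probability mass,
#' found by sliding a fixed-mass window over the sorted samples.
#'
#' @param samples Numeric vector, at least 20 values.
#' @param mass Probability mass in (0, 1), default 0.95.
#' @return Numeric vector `c(lo, hi)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  samples <- samples[is.finite(samples)]
  if (length(samples) < 20) stop("hdi needs at least 20 samples")
  x <- sort(samples)
  n <- length(x)
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(lo = x[1], hi = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lo = x[i], hi = x[i + k])
}

#' Library of simulated configurations with realized correlations
#'
#' Samples configurations of one structure and simulates one dataset per
#' configuration at sample size `sample_size` (ideally comparable to the
#' observed study size), recording each configuration's causal, error, and
#' true latent correlations alongside the realized *estimated* data
#' correlations of its finite-sample dataset — the quantities the bootstrap
#' filter matches against.
#'
#' @param structure Generating structure (constrained).
#' @param n_configs Library size.
#' @param sample_size Per-dataset sample size.
#' @param seed Master seed.
#' @param beta_shape Beta shape parameters of the sampled correlations.
#' @return Data frame of class `"config_library"` with one row per
#'   configuration: causal (`rho_xm`, `rho_xy`, `rho_ym`), error (`err_x`,
#'   `err_m`, `err_y`), latent (`rho_xu`, `rho_mu`, `rho_yu`) parameters and
#'   realized correlations (`r_xm`, `r_xy`, `r_ym`).
#' @export
config_library <- function(structure, n_configs = 10000, sample_size = 200,
                           seed = 1, beta_shape = c(5, 1.25)) {
  structure <- match.arg(structure, c("Causal", "Independent", "Reactive"))
  seeds <- .spawn_seeds(seed, 2L)
  arm <- sim_design(structure = structure, n_configs = n_configs,
                    sample_size = sample_size, beta_shape = beta_shape,
                    seed = seeds[1])
  configs <- sample_configs(arm)
  cors <- .simulate_study_cors(arm, seeds[2])
  par <- t(vapply(configs, function(cf) {
    c(rho_xm = cf$causal$rho_xm, rho_xy = cf$causal$rho_xy,
      rho_ym = cf$causal$rho_ym, err_x = cf$err_x, err_m = cf$err_m,
      err_y = cf$err_y, as.numeric(latent_from_config(cf)))
  }, numeric(9)))
  out <- data.frame(structure = structure, par, cors)
  class(out) <- c("config_library", "data.frame")
  attr(out, "sample_size") <- sample_size
  attr(out, "seed") <- seed
  out
}

#' Filter a configuration library against a bootstrap region
#'
#' Keeps the configurations whose realized estimated data correlations fall
#' inside all three bootstrap region intervals simultaneously, and summarizes
#' the surviving causal, error, latent, and data correlations by median and
#' 95% highest density interval. An empty survivor set is returned explicitly
#' (`n_survivors = 0`, no summaries): at library resolution, the assumed
#' structure is inconsistent with the observed data. Shrinking the region can
#' only remove survivors, never add them.
#'
#' @param library A [config_library()] for the assumed structure.
#' @param boot A [boot_cors()] from the observed data.
#' @param hdi_mass Mass of the reported highest density intervals. When fewer
#'   than 20 configurations survive, the plain range is reported instead.
#' @return Object of class `"feasible_set"`: the assumed structure, the
#'   surviving rows, and a `summaries` data frame (parameter, median, lo, hi).
#'   `as.data.frame()` returns the summaries with the survivor count attached.
#' @export
filter_configs <- function(library, boot, hdi_mass = 0.95) {
  stopifnot(inherits(library, "config_library"), inherits(boot, "boot_cors"))
  reg <- boot$region
  keep <- library$r_xm >= reg["r_xm", "lo"] & library$r_xm <= reg["r_xm", "hi"] &
          library$r_xy >= reg["r_xy", "lo"] & library$r_xy <= reg["r_xy", "hi"] &
          library$r_ym >= reg["r_ym", "lo"] & library$r_ym <= reg["r_ym", "hi"]
  survivors <- library[keep, , drop = FALSE]
  params <- c("rho_xm", "rho_xy", "rho_ym", "err_x", "err_m", "err_y",
              "rho_xu", "rho_mu", "rho_yu", "r_xm", "r_xy", "r_ym")
  summaries <- NULL
  if (nrow(survivors) > 0) {
    summaries <- do.call(rbind, lapply(params, function(p) {
      v <- survivors[[p]]
      iv <- if (length(v) >= 20) hdi(v, mass = hdi_mass) else range(v)
      data.frame(parameter = p, median = stats::median(v),
                 lo = iv[1], hi = iv[2], stringsAsFactors = FALSE)
    }))
    rownames(summaries) <- NULL
  }
  structure(list(structure = library$structure[1], survivors = survivors,
                 summaries = summaries, n_survivors = nrow(survivors),
                 region = reg, hdi_mass = hdi_mass),
            class = "feasible_set")
}

#' @export
print.feasible_set <- function(x, ...) {
  cat(sprintf("<feasible_set> assumed %s: %d surviving configs\n",
              x$structure, x$n_survivors))
  if (x$n_survivors == 0) {
    cat("no feasible configs: the assumed structure is inconsistent with the",
        "data at library resolution\n")
  } else {
    df <- x$summaries
    df[-1] <- lapply(df[-1], round, 3)
    print(df)
  }
  invisible(x)
}

#' @export
as.data.frame.feasible_set <- function(x, ...) {
  if (x$n_survivors == 0) {
    return(data.frame(structure = x$structure, parameter = NA_character_,
                      median = NA_real_, lo = NA_real_, hi = NA_real_,
                      n_survivors = 0L))
  }
  cbind(structure = x$structure, x$summaries, n_survivors = x$n_survivors)
}
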