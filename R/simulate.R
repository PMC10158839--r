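# Synthetic triplet generator: samples measurement-error configurations with
# Beta-distributed correlations and simulates finite-sample standardized
# linear-Gaussian triplets, optionally with a multistate (haplotype-dosage)
# genotype.

#' Simulation design
#'
#' Describes one arm of a simulation study: the generating structure, how many
#' configurations to draw, the per-dataset sample size, and the Beta shape
#' parameters for the causal and error correlations. The default
#' Beta(5, 1.25), with mean 0.8 and 95% highest density interval (0.5, 1),
#' places most mass on moderate-to-strong correlations while allowing weak
#' ones — a realistic regime for local QTL effects and modern expression /
#' proteomics assays.
#'
#' @param structure Generating structure, or a vector of structures for
#'   multi-arm studies (default all three constrained structures).
#' @param n_configs Number of configurations per structure (at least 1).
#' @param sample_size Observations per simulated dataset (at least 10).
#' @param beta_shape Length-2 shape parameters of the Beta distribution.
#' @param seed Master seed; all derived randomness is reproducible from it.
#' @param x_kind `"gaussian"` for a univariate standard-normal genotype score,
#'   `"multistate"` for a one-hot haplotype-state block.
#' @param n_states Number of states when `x_kind = "multistate"`.
#' @return Object of class `"sim_design"`.
#' @export
sim_design <- function(structure = c("Causal", "Independent", "Reactive"),
                       n_configs = 10000, sample_size = 200,
                       beta_shape = c(5, 1.25), seed = 1,
                       x_kind = c("gaussian", "multistate"), n_states = 8) {
  structure <- match.arg(structure, causal_structures(), several.ok = TRUE)
  x_kind <- match.arg(x_kind)
  stopifnot(n_configs >= 1, sample_size >= 10,
            length(beta_shape) == 2, all(beta_shape > 0), n_states >= 2)
  if ("Complex" %in% structure) {
    stop("simulation designs cover the constrained structures only")
  }
  structure(list(structure = structure, n_configs = as.integer(n_configs),
                 sample_size = as.integer(sample_size),
                 beta_shape = as.numeric(beta_shape),
                 seed = as.integer(seed), x_kind = x_kind,
                 n_states = as.integer(n_states)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("<sim_design> %s | %d configs x N=%d | rho ~ Beta(%g, %g) | x=%s\n",
              paste(x$structure, collapse = "/"), x$n_configs, x$sample_size,
              x$beta_shape[1], x$beta_shape[2], x$x_kind))
  invisible(x)
}

# Derive independent-looking substream seeds from a master seed without
# disturbing more than one RNG state; values stay below 2^31.
.spawn_seeds <- function(master, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(2147483646L, k)
}

#' Sample measurement-error configurations
#'
#' Draws `n_configs` configurations of a single constrained structure: the two
#' free causal correlations (the edges present in the structure) and the three
#' error correlations are iid Beta(`beta_shape`), and the third causal
#' correlation is set by the product constraint, so every configuration
#' satisfies [structure_constraint()] by construction. Deterministic given the
#' design seed.
#'
#' @param design A [sim_design()] whose `structure` is a single constrained
#'   structure.
#' @return List of [me_config()] objects, length `n_configs`.
#' @export
sample_configs <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (length(design$structure) != 1) {
    stop("sample_configs needs a single-structure design")
  }
  st <- design$structure
  set.seed(design$seed)
  draws <- matrix(stats::rbeta(5L * design$n_configs,
                               design$beta_shape[1], design$beta_shape[2]),
                  ncol = 5, byrow = TRUE)
  lapply(seq_len(design$n_configs), function(i) {
    d <- draws[i, ]
    switch(st,
      Causal = me_config("Causal", rho_xm = d[1], rho_ym = d[2],
                         err_x = d[3], err_m = d[4], err_y = d[5]),
      Independent = me_config("Independent", rho_xm = d[1], rho_xy = d[2],
                              err_x = d[3], err_m = d[4], err_y = d[5]),
      Reactive = me_config("Reactive", rho_xy = d[1], rho_ym = d[2],
                           err_x = d[3], err_m = d[4], err_y = d[5]))
  })
}

# child = rho * parent + sqrt(1 - rho^2) * fresh standard normal; keeps unit
# population variance when the parent has it
.prop <- function(parent, rho) rho * parent + sqrt(1 - rho^2) * stats::rnorm(length(parent))

#' Simulate a finite-sample triplet dataset
#'
#' Generates `n` observations from a measurement-error configuration. On the
#' Gaussian path, the exogenous causal variable X* is standard normal and each
#' downstream variable (causal children in the structure's topological order,
#' then each measured variable from its causal counterpart) equals
#' `rho * parent + sqrt(1 - rho^2) * noise`, so every continuous variable has
#' population mean 0 and variance 1.
#'
#' On the multistate path, X* is a state drawn uniformly from `n_states`
#' categories, reported as one-hot dosage columns `x1..xk`. A mean-centered
#' state-effect vector (drawn once per dataset and shared by all edges out of
#' X*, so product constraints carry over) is scaled so that the squared
#' multiple correlation between state and child equals `rho^2`. Measurement
#' error on the genotype is a state misassignment: the measured state equals
#' the true state with probability `err_x` and is uniform otherwise, which
#' reproduces a canonical correlation of `err_x * rho` between the measured
#' dosage block and a child.
#'
#' @param config An [me_config()] with a constrained structure.
#' @param n Number of observations (at least 10).
#' @param seed Optional seed set before simulation.
#' @param x_kind `"gaussian"` or `"multistate"`.
#' @param n_states States for the multistate genotype.
#' @return A `triplet_data` data frame with columns `x` (or `x1..xk`), `m`,
#'   `y`; the generating configuration is attached as attribute `"truth"`.
#' @export
simulate_triplet <- function(config, n, seed = NULL,
                             x_kind = c("gaussian", "multistate"),
                             n_states = 8) {
  stopifnot(inherits(config, "me_config"), n >= 10)
  x_kind <- match.arg(x_kind)
  if (config$structure == "Complex") {
    stop("simulation covers the constrained structures only")
  }
  if (!is.null(seed)) set.seed(seed)
  cc <- config$causal
  if (x_kind == "gaussian") {
    xs <- stats::rnorm(n)
    x_drive <- xs
  } else {
    state <- sample.int(n_states, n, replace = TRUE)
    v <- stats::rnorm(n_states)
    v <- v - mean(v)
    v <- v / sqrt(mean(v^2))       # unit variance over uniform states
    x_drive <- v[state]            # standardized effect of the true state
  }
  if (config$structure == "Causal") {
    ms <- .prop(x_drive, cc$rho_xm)
    ys <- .prop(ms, cc$rho_ym)
  } else if (config$structure == "Independent") {
    ms <- .prop(x_drive, cc$rho_xm)
    ys <- .prop(x_drive, cc$rho_xy)
  } else {
    ys <- .prop(x_drive, cc$rho_xy)
    ms <- .prop(ys, cc$rho_ym)
  }
  m <- .prop(ms, config$err_m)
  y <- .prop(ys, config$err_y)
  if (x_kind == "gaussian") {
    x <- .prop(xs, config$err_x)
    dat <- data.frame(x = x, m = m, y = y)
    x_cols <- "x"
  } else {
    keep <- stats::runif(n) < config$err_x
    obs_state <- ifelse(keep, state, sample.int(n_states, n, replace = TRUE))
    dosage <- matrix(0, n, n_states,
                     dimnames = list(NULL, paste0("x", seq_len(n_states))))
    dosage[cbind(seq_len(n), obs_state)] <- 1
    dat <- data.frame(dosage, m = m, y = y)
    x_cols <- colnames(dosage)
  }
  triplet_data(dat, x_cols = x_cols, truth = config, x_kind = x_kind)
}

#' @describeIn simulate_triplet `simulate()` method for configurations:
#'   returns a list of `nsim` datasets with seeds derived from `seed`.
#' @param object An `me_config` (for the `simulate` method).
#' @param nsim Number of datasets.
#' @param ... Passed on to `simulate_triplet()`.
#' @export
simulate.me_config <- function(object, nsim = 1, seed = NULL, n = 200, ...) {
  seeds <- if (is.null(seed)) rep(list(NULL), nsim)
           else as.list(.spawn_seeds(seed, nsim))
  lapply(seq_len(nsim), function(i) {
    simulate_triplet(object, n = n, seed = seeds[[i]], ...)
  })
}

#' Triplet dataset container
#'
#' Wraps a data frame of one row per sample with mediator column `m`, target
#' column `y`, genotype column(s) `x` or `x1..xk` (multistate dosage rows must
#' be nonnegative and sum to 1), and optional covariate columns. Values must
#' be complete.
#'
#' @param data A data frame.
#' @param x_cols Genotype column name(s).
#' @param m,y Mediator / target column names.
#' @param covariates Optional covariate column names.
#' @param truth Optional generating [me_config()] for closed-loop evaluation.
#' @param x_kind `"gaussian"` or `"multistate"`; inferred from `x_cols` length
#'   when missing.
#' @return Object of class `c("triplet_data", "data.frame")`.
#' @export
triplet_data <- function(data, x_cols = "x", m = "m", y = "y",
                         covariates = character(0), truth = NULL,
                         x_kind = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(x_cols, m, y, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(data[need])) stop("triplet data must not contain missing values")
  if (is.null(x_kind)) x_kind <- if (length(x_cols) > 1) "multistate" else "gaussian"
  if (x_kind == "multistate") {
    xb <- as.matrix(data[x_cols])
    if (any(xb < 0) || any(abs(rowSums(xb) - 1) > 1e-8)) {
      stop("multistate dosage rows must be nonnegative and sum to 1")
    }
  }
  out <- data[c(need, setdiff(names(data), need))]
  structure(out, class = c("triplet_data", "data.frame"),
            x_cols = x_cols, m_col = m, y_col = y,
            covariate_cols = covariates, truth = truth, x_kind = x_kind)
}

#' @export
print.triplet_data <- function(x, ...) {
  cat(sprintf("<triplet_data> N=%d, x=%s (%s)%s%s\n", nrow(x),
              paste(attr(x, "x_cols"), collapse = ","), attr(x, "x_kind"),
              if (length(attr(x, "covariate_cols")))
                paste0(", covariates=", paste(attr(x, "covariate_cols"), collapse = ","))
              else "",
              if (!is.null(attr(x, "truth")))
                paste0(", truth=", attr(x, "truth")$structure) else ""))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Write / read triplet datasets as CSV
#'
#' Plain-text round trip for [triplet_data()]: header columns `x` (or
#' `x1..xk`), `m`, `y`, and any covariates. The generating configuration, if
#' present, can be stored in a sidecar file via [write_me_config()].
#'
#' @param data A `triplet_data`.
#' @param path CSV path.
#' @param x_cols,m,y,covariates Column names, as in [triplet_data()]; for
#'   `read_triplets`, `x_cols = NULL` auto-detects `x` or `x1..xk`.
#' @return `write_triplets` returns `path` invisibly; `read_triplets` a
#'   `triplet_data`.
#' @export
write_triplets <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_triplets
#' @export
read_triplets <- function(path, x_cols = NULL, m = "m", y = "y",
                          covariates = character(0)) {
  df <- utils::read.csv(path)
  if (is.null(x_cols)) {
    x_cols <- if ("x" %in% names(df)) "x"
              else grep("^x[0-9]+$", names(df), value = TRUE)
    if (!length(x_cols)) stop("no genotype columns 'x' or 'x1..xk' found")
  }
  triplet_data(df, x_cols = x_cols, m = m, y = y, covariates = covariates)
}
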