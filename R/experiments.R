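# Simulation-study orchestration: classification-rate tables across
# structures and option sets, and selection-rate curves as a function of the
# middle variable's latent correlation.

#' Classification-rate study
#'
#' For each requested structure, samples configurations (causal and error
#' correlations iid Beta), simulates one dataset per configuration at the
#' design sample size, classifies every dataset with the requested option set,
#' and tabulates the percentage of each selected label per generating
#' structure. Deterministic given the design seed; per-configuration datasets
#' use seeds derived from it, so results do not depend on evaluation order.
#'
#' @param design A [sim_design()]; its `structure` field gives the study arms.
#' @param option_set `"three_choice"` or `"expanded"`.
#' @param priors A [bms_priors()].
#' @param cors Optional precomputed [study_correlations()] for this design, so
#'   one simulation pass can be tabulated under several option sets.
#' @return Object of class `"classification_table"`: a labels-by-structures
#'   matrix of percentages (columns sum to 100) with the design stored in
#'   attributes. `summary()` reports the pooled correct-classification rate,
#'   the mean wrong-constrained-model rate, and (expanded) the Complex rate.
#' @examples
#' \donttest{
#' tab <- run_classification_study(sim_design(n_configs = 500, seed = 3))
#' tab
#' summary(tab)
#' }
#' @export
run_classification_study <- function(design,
                                     option_set = c("three_choice", "expanded"),
                                     priors = bms_priors(), cors = NULL) {
  stopifnot(inherits(design, "sim_design"))
  option_set <- match.arg(option_set)
  if (is.null(cors)) cors <- study_correlations(design)
  structures <- design$structure
  labels <- if (option_set == "three_choice") {
    c("Causal", "Independent", "Reactive")
  } else {
    c("Causal", "Independent", "Reactive", "Complex", "Other")
  }
  tab <- matrix(0, length(labels), length(structures),
                dimnames = list(labels, structures))
  for (j in seq_along(structures)) {
    sub <- cors[cors$structure == structures[j], , drop = FALSE]
    sel <- classify_cors(sub$r_xm, sub$r_xy, sub$r_ym,
                         n = design$sample_size, options = option_set,
                         priors = priors)
    counts <- table(factor(sel, levels = labels))
    tab[, j] <- 100 * as.numeric(counts) / nrow(sub)
  }
  structure(tab, class = c("classification_table", "matrix"),
            sample_size = design$sample_size, option_set = option_set,
            n_configs = design$n_configs, seed = design$seed)
}

#' Simulated study correlations
#'
#' Runs the simulation half of a classification study: for every structure in
#' the design, samples configurations, simulates one dataset each, and
#' returns the estimated data correlations — the coordinates on which all
#' univariate model-selection outcomes depend. Deterministic given the design
#' seed and independent of evaluation order (each dataset draws from its own
#' derived seed).
#'
#' @param design A [sim_design()] with the univariate gaussian genotype.
#' @return Data frame with columns `structure`, `config` (index within the
#'   structure arm), `r_xm`, `r_xy`, `r_ym`.
#' @export
study_correlations <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (design$x_kind != "gaussian") {
    stop("classification studies use the univariate gaussian genotype")
  }
  structures <- design$structure
  arm_seeds <- .spawn_seeds(design$seed, 2L * length(structures))
  out <- vector("list", length(structures))
  for (j in seq_along(structures)) {
    arm <- sim_design(structure = structures[j], n_configs = design$n_configs,
                      sample_size = design$sample_size,
                      beta_shape = design$beta_shape,
                      seed = arm_seeds[2L * j - 1L])
    cors <- .simulate_study_cors(arm, arm_seeds[2L * j])
    out[[j]] <- data.frame(structure = structures[j],
                           config = seq_len(nrow(cors)), cors)
  }
  do.call(rbind, out)
}

# simulate one dataset per config of a single-structure design and return the
# matrix of estimated data correlations
.simulate_study_cors <- function(arm, data_seed) {
  configs <- sample_configs(arm)
  seeds <- .spawn_seeds(data_seed, length(configs))
  out <- matrix(NA_real_, length(configs), 3,
                dimnames = list(NULL, c("r_xm", "r_xy", "r_ym")))
  for (i in seq_along(configs)) {
    d <- simulate_triplet(configs[[i]], n = arm$sample_size, seed = seeds[i])
    out[i, ] <- c(stats::cor(d$x, d$m), stats::cor(d$x, d$y),
                  stats::cor(d$y, d$m))
  }
  out
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf("Classification rates (%%), %s options, N=%d, %d configs/structure\n",
              attr(x, "option_set"), attr(x, "sample_size"),
              attr(x, "n_configs")))
  m <- round(unclass(x), 2)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(m)
  invisible(x)
}

#' @export
summary.classification_table <- function(object, ...) {
  structures <- colnames(object)
  diag_rates <- vapply(structures, function(s) object[s, s], 0)
  constrained <- intersect(rownames(object),
                           c("Causal", "Independent", "Reactive"))
  wrong <- unlist(lapply(structures, function(s) {
    object[setdiff(constrained, s), s]
  }))
  out <- list(overall_correct = mean(diag_rates),
              per_structure_correct = diag_rates,
              wrong_constrained_mean = mean(wrong))
  if ("Complex" %in% rownames(object)) {
    out$complex_rate <- mean(object["Complex", ])
    out$other_rate <- mean(object["Other", ])
  }
  class(out) <- "summary.classification_table"
  out
}

#' @export
print.summary.classification_table <- function(x, ...) {
  cat(sprintf("Overall correct: %.2f%%\n", x$overall_correct))
  cat("Per structure:",
      paste(sprintf("%s %.2f%%", names(x$per_structure_correct),
                    x$per_structure_correct), collapse = ", "), "\n")
  cat(sprintf("Mean wrong-constrained-model rate: %.2f%%\n",
              x$wrong_constrained_mean))
  if (!is.null(x$complex_rate)) {
    cat(sprintf("Mean Complex rate: %.2f%%; mean Other rate: %.2f%%\n",
                x$complex_rate, x$other_rate))
  }
  invisible(x)
}

#' Selection rates versus the middle latent correlation
#'
#' Bins configurations of one generating structure by the true latent
#' correlation of the middle variable (e.g. `rho_mu` for the Causal
#' structure), stratifies them by whether `rho_xu` or `rho_yu` dominates, and
#' reports the fraction of simulated datasets assigned each label per bin and
#' sample size. As the middle latent correlation approaches 1, three-choice
#' selection recovers the generating structure with probability approaching 1;
#' under the expanded options the Complex model dominates at moderate values.
#' Empty bins are absent from the output rather than reported as zero.
#'
#' @param structure Generating structure (constrained).
#' @param option_set `"three_choice"` or `"expanded"`.
#' @param sample_sizes Vector of dataset sizes to sweep.
#' @param n_configs Configurations drawn for the sweep.
#' @param bin_width Width of the latent-correlation bins (bins are centered on
#'   multiples of `bin_width`).
#' @param seed Master seed.
#' @param beta_shape Beta shape parameters for the sampled correlations.
#' @param priors A [bms_priors()].
#' @return Data frame of class `"latent_rate_curve"` with columns `n`,
#'   `stratum` (`"xu>yu"` or `"yu>=xu"`), `bin` (bin center of the middle
#'   latent correlation), `label`, `rate`, and `count` (datasets in the bin).
#' @export
rate_vs_latent_curve <- function(structure = "Causal",
                                 option_set = c("three_choice", "expanded"),
                                 sample_sizes = c(200, 1000, 5000),
                                 n_configs = 2000, bin_width = 0.05, seed = 1,
                                 beta_shape = c(5, 1.25),
                                 priors = bms_priors()) {
  structure <- match.arg(structure, c("Causal", "Independent", "Reactive"))
  option_set <- match.arg(option_set)
  seeds <- .spawn_seeds(seed, length(sample_sizes) + 1L)
  arm <- sim_design(structure = structure, n_configs = n_configs,
                    sample_size = max(10, min(sample_sizes)),
                    beta_shape = beta_shape, seed = seeds[1])
  configs <- sample_configs(arm)
  lat <- t(vapply(configs, function(cf) as.numeric(latent_from_config(cf)),
                  numeric(3)))
  mid <- switch(structure, Causal = lat[, "rho_mu"],
                Independent = lat[, "rho_xu"], Reactive = lat[, "rho_yu"])
  bin <- round(mid / bin_width) * bin_width
  stratum <- ifelse(abs(lat[, "rho_xu"]) > abs(lat[, "rho_yu"]),
                    "xu>yu", "yu>=xu")
  res <- list()
  for (k in seq_along(sample_sizes)) {
    N <- sample_sizes[k]
    dseeds <- .spawn_seeds(seeds[k + 1L], n_configs)
    cors <- matrix(NA_real_, n_configs, 3)
    for (i in seq_len(n_configs)) {
      d <- simulate_triplet(configs[[i]], n = N, seed = dseeds[i])
      cors[i, ] <- c(stats::cor(d$x, d$m), stats::cor(d$x, d$y),
                     stats::cor(d$y, d$m))
    }
    sel <- classify_cors(cors[, 1], cors[, 2], cors[, 3], n = N,
                         options = option_set, priors = priors)
    agg <- stats::aggregate(
      list(count = rep(1L, n_configs)),
      by = list(n = rep(N, n_configs), stratum = stratum, bin = bin,
                label = sel), FUN = sum)
    tot <- stats::aggregate(list(total = agg$count),
                            by = agg[c("n", "stratum", "bin")], FUN = sum)
    agg <- merge(agg, tot)
    agg$rate <- agg$count / agg$total
    res[[k]] <- agg[c("n", "stratum", "bin", "label", "rate", "count")]
  }
  out <- do.call(rbind, res)
  out <- out[order(out$n, out$stratum, out$bin, out$label), ]
  rownames(out) <- NULL
  class(out) <- c("latent_rate_curve", "data.frame")
  attr(out, "structure") <- structure
  attr(out, "option_set") <- option_set
  out
}

#' @export
plot.latent_rate_curve <- function(x, label = attr(x, "structure"), ...) {
  sub <- x[x$label == label, ]
  ns <- sort(unique(sub$n))
  graphics::plot(NULL, xlim = range(x$bin), ylim = c(0, 1),
                 xlab = "middle latent correlation (binned)",
                 ylab = sprintf("P(select %s)", label),
                 main = sprintf("%s simulations, %s options",
                                attr(x, "structure"), attr(x, "option_set")))
  for (i in seq_along(ns)) {
    for (strat in unique(sub$stratum)) {
      s <- sub[sub$n == ns[i] & sub$stratum == strat, ]
      s <- s[order(s$bin), ]
      graphics::lines(s$bin, s$rate, col = i,
                      lty = if (strat == "xu>yu") 1 else 2)
    }
  }
  graphics::legend("topleft", legend = paste0("N=", ns), col = seq_along(ns),
                   lty = 1, bty = "n")
  invisible(x)
}
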