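# Single-latent-factor reparameterization: the constrained measurement-error
# models (five free parameters, three observables) collapse to a three
# parameter model in which one latent variable U drives all three measured
# variables, rho_pair = rho_pU * rho_qU for each pair.

#' Latent correlation triple
#'
#' The correlations of the measured variables X, M, Y with the single latent
#' factor U. Unlike causal and error correlations, these are estimable from
#' data: their pairwise products reproduce the data correlations.
#'
#' @param rho_xu,rho_mu,rho_yu Latent correlations, magnitudes at most 1.
#' @param heywood Flag set by [estimate_latent()] when a finite-sample
#'   estimate exceeded 1 in magnitude and was clipped.
#' @return Object of class `"latent_triple"`.
#' @export
latent_triple <- function(rho_xu, rho_mu, rho_yu, heywood = FALSE) {
  vals <- c(rho_xu, rho_mu, rho_yu)
  if (any(!is.finite(vals)) || any(abs(vals) > 1 + 1e-12)) {
    stop("latent correlations must have magnitude at most 1")
  }
  structure(list(rho_xu = unname(rho_xu), rho_mu = unname(rho_mu),
                 rho_yu = unname(rho_yu), heywood = isTRUE(heywood)),
            class = "latent_triple")
}

#' @export
print.latent_triple <- function(x, ...) {
  cat(sprintf("<latent_triple> rho_xu=%.4g rho_mu=%.4g rho_yu=%.4g%s\n",
              x$rho_xu, x$rho_mu, x$rho_yu,
              if (x$heywood) "  [Heywood: clipped]" else ""))
  invisible(x)
}

#' @export
as.double.latent_triple <- function(x, ...) {
  c(rho_xu = x$rho_xu, rho_mu = x$rho_mu, rho_yu = x$rho_yu)
}

#' Latent correlations of a constrained configuration
#'
#' Maps a Causal, Independent, or Reactive measurement-error configuration to
#' its latent-factor representation. The middle variable's latent correlation
#' equals its error correlation; each non-middle variable's latent correlation
#' is the product of its error correlation and a causal correlation:
#'
#' | structure | rho_xu | rho_mu | rho_yu |
#' |---|---|---|---|
#' | Causal | err_x * rho_xm | err_m | err_y * rho_ym |
#' | Independent | err_x | err_m * rho_xm | err_y * rho_xy |
#' | Reactive | err_x * rho_xy | err_m * rho_ym | err_y |
#'
#' Pairwise products of the result equal the configuration's implied data
#' correlations exactly.
#'
#' @param config An [me_config()] with a constrained structure.
#' @return A [latent_triple()].
#' @export
latent_from_config <- function(config) {
  stopifnot(inherits(config, "me_config"))
  if (config$structure == "Complex") {
    stop("no single-latent representation: the Complex structure does not ",
         "collapse to one factor")
  }
  cc <- config$causal
  switch(config$structure,
    Causal = latent_triple(config$err_x * cc$rho_xm,
                           config$err_m,
                           config$err_y * cc$rho_ym),
    Independent = latent_triple(config$err_x,
                                config$err_m * cc$rho_xm,
                                config$err_y * cc$rho_xy),
    Reactive = latent_triple(config$err_x * cc$rho_xy,
                             config$err_m * cc$rho_ym,
                             config$err_y))
}

#' Closed-form latent-correlation estimator
#'
#' Inverts the single-factor product equations by the tetrad formulas
#' \deqn{|\rho_{XU}| = \sqrt{|\rho_{XY}\rho_{XM}/\rho_{YM}|}}
#' (and cyclically for M and Y). Signs are assigned so that pairwise products
#' reproduce the signs of the input correlations, with the convention
#' `rho_mu >= 0` (the latent factor's orientation is arbitrary; fixing M's
#' sign makes the output deterministic). Estimates whose magnitude exceeds 1 —
#' possible in finite samples (Heywood cases) — are clipped to 1 and flagged
#' rather than rejected, so resampling pipelines do not crash.
#'
#' @param data A `corr_triple` with role `"data"` or `"estimated"`, or a
#'   numeric vector `c(rho_xy, rho_xm, rho_ym)`.
#' @param min_abs Identification floor: all three input magnitudes must be at
#'   least this large for the tetrad ratios to be meaningful.
#' @return A [latent_triple()]; its `heywood` field records clipping.
#' @export
estimate_latent <- function(data, min_abs = 1e-6) {
  v <- .triple_values(data)
  if (inherits(data, "corr_triple") && data$role == "causal") {
    stop("latent correlations are estimated from data correlations, not causal ones")
  }
  if (any(abs(v) < min_abs)) {
    stop("latent model unidentified: |correlation| below min_abs = ", min_abs)
  }
  if (prod(v) <= 0) {
    stop("sign-inconsistent with single factor: rho_xy * rho_xm * rho_ym must be positive")
  }
  xu <- sqrt(abs(v[["rho_xy"]] * v[["rho_xm"]] / v[["rho_ym"]]))
  mu <- sqrt(abs(v[["rho_xm"]] * v[["rho_ym"]] / v[["rho_xy"]]))
  yu <- sqrt(abs(v[["rho_xy"]] * v[["rho_ym"]] / v[["rho_xm"]]))
  heywood <- any(c(xu, mu, yu) > 1)
  xu <- min(xu, 1); mu <- min(mu, 1); yu <- min(yu, 1)
  # rho_mu >= 0, so the signs of rho_xm and rho_ym transfer to X and Y
  xu <- xu * sign(v[["rho_xm"]])
  yu <- yu * sign(v[["rho_ym"]])
  latent_triple(xu, mu, yu, heywood = heywood)
}

#' Diagnose the asymptotic outcome of three-choice model selection
#'
#' In large samples, three-choice model selection picks the structure whose
#' middle variable has the strongest latent correlation: strongest `|rho_mu|`
#' selects Causal, strongest `|rho_xu|` Independent, strongest `|rho_yu|`
#' Reactive. Given latent correlations and an assumed generating structure,
#' reports which correlation dominates, the asymptotically selected model, and
#' whether that selection is consistent with the assumption.
#'
#' @param latent A [latent_triple()].
#' @param assumed The assumed generating structure (constrained).
#' @param margin Tie margin: if the top two magnitudes differ by no more than
#'   this, the verdict is `"ambiguous"`. Default 0 (strict argmax).
#' @return Object of class `"latent_diagnosis"`: a list with `strongest`
#'   (`"rho_xu"`, `"rho_mu"`, or `"rho_yu"`), `selected`, `verdict`
#'   (`"consistent"`, `"inconsistent"`, or `"ambiguous"`), the latent
#'   correlations and flags. `as.data.frame()` gives a flat one-row summary.
#' @export
diagnose_consistency <- function(latent, assumed, margin = 0) {
  stopifnot(inherits(latent, "latent_triple"))
  assumed <- match.arg(assumed, c("Causal", "Independent", "Reactive"))
  mags <- abs(c(rho_xu = latent$rho_xu, rho_mu = latent$rho_mu,
                rho_yu = latent$rho_yu))
  ord <- order(mags, decreasing = TRUE)
  strongest <- names(mags)[ord[1]]
  selected <- c(rho_xu = "Independent", rho_mu = "Causal",
                rho_yu = "Reactive")[[strongest]]
  ambiguous <- (mags[ord[1]] - mags[ord[2]]) <= margin
  verdict <- if (ambiguous) "ambiguous"
             else if (selected == assumed) "consistent" else "inconsistent"
  structure(list(latent = latent, assumed = assumed, strongest = strongest,
                 selected = if (ambiguous) NA_character_ else selected,
                 verdict = verdict, margin = margin),
            class = "latent_diagnosis")
}

#' @export
print.latent_diagnosis <- function(x, ...) {
  cat(sprintf("<latent_diagnosis> assumed=%s strongest=%s selected=%s verdict=%s\n",
              x$assumed, x$strongest,
              ifelse(is.na(x$selected), "-", x$selected), x$verdict))
  invisible(x)
}

#' @export
as.data.frame.latent_diagnosis <- function(x, ...) {
  data.frame(rho_xu = x$latent$rho_xu, rho_mu = x$latent$rho_mu,
             rho_yu = x$latent$rho_yu, heywood = x$latent$heywood,
             assumed = x$assumed, strongest = x$strongest,
             selected = x$selected, verdict = x$verdict,
             stringsAsFactors = FALSE)
}
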