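# Measurement-error model for a triplet (X, M, Y): causal correlations among
# the error-free variables X*, M*, Y*, error correlations linking each causal
# variable to its measurement, and the data correlations they induce among the
# measured variables.

#' Recognized causal structures
#'
#' The four mediation structures considered for a triplet (X, M, Y):
#' `"Causal"` (complete mediation, no direct X->Y edge), `"Independent"`
#' (no M->Y edge), `"Reactive"` (reversed Y->M edge), and `"Complex"`
#' (partial mediation, all edges present).
#'
#' @return Character vector of the four structure labels.
#' @export
causal_structures <- function() c("Causal", "Independent", "Reactive", "Complex")

#' Middle variable of a constrained structure
#'
#' Each constrained structure has a unique middle variable that separates the
#' other two: M for Causal, X for Independent, Y for Reactive. The Complex
#' structure has none.
#'
#' @param structure One of `causal_structures()`.
#' @return `"X"`, `"M"`, `"Y"`, or `NA` for Complex.
#' @export
middle_variable <- function(structure) {
  structure <- match.arg(structure, causal_structures())
  switch(structure,
         Causal = "M", Independent = "X", Reactive = "Y",
         Complex = NA_character_)
}

#' Correlation triple for a triplet
#'
#' Bundles the three pairwise correlations among (X, M, Y) together with the
#' role they play: `"causal"` (among the error-free variables), `"data"`
#' (population correlations among measured variables), or `"estimated"`
#' (finite-sample estimates). Causal and data triples must form a positive
#' semidefinite correlation matrix; estimated triples are allowed to violate
#' PSD since sample noise can push them over the boundary.
#'
#' @param rho_xy,rho_xm,rho_ym Correlations in \[-1, 1\].
#' @param role One of `"data"`, `"causal"`, `"estimated"`.
#' @param eig_tol Eigenvalue tolerance for the PSD check.
#' @return An object of class `"corr_triple"`.
#' @export
corr_triple <- function(rho_xy, rho_xm, rho_ym,
                        role = c("data", "causal", "estimated"),
                        eig_tol = 1e-10) {
  role <- match.arg(role)
  vals <- c(rho_xy = rho_xy, rho_xm = rho_xm, rho_ym = rho_ym)
  if (any(!is.finite(vals))) stop("correlations must be finite")
  if (any(abs(vals) > 1)) {
    stop("correlations must lie in [-1, 1]; got (",
         paste(signif(vals, 4), collapse = ", "), ")")
  }
  obj <- structure(
    list(rho_xy = unname(rho_xy), rho_xm = unname(rho_xm),
         rho_ym = unname(rho_ym), role = role),
    class = "corr_triple")
  if (role != "estimated" && !is_psd(obj, eig_tol = eig_tol)) {
    stop("violated constraint: correlation matrix of (",
         paste(signif(vals, 4), collapse = ", "),
         ") is not positive semidefinite")
  }
  obj
}

#' @export
print.corr_triple <- function(x, ...) {
  cat(sprintf("<corr_triple role=%s> rho_xy=%.4g rho_xm=%.4g rho_ym=%.4g\n",
              x$role, x$rho_xy, x$rho_xm, x$rho_ym))
  invisible(x)
}

#' @export
as.double.corr_triple <- function(x, ...) {
  c(rho_xy = x$rho_xy, rho_xm = x$rho_xm, rho_ym = x$rho_ym)
}

#' Positive-semidefiniteness of a correlation triple
#'
#' Checks whether the 3x3 unit-diagonal matrix implied by the three pairwise
#' correlations is positive semidefinite, i.e. whether its smallest eigenvalue
#' is at least `-eig_tol`. Matrices within tolerance of the boundary are
#' accepted.
#'
#' @param triple A `corr_triple`, or a numeric vector `c(rho_xy, rho_xm,
#'   rho_ym)`.
#' @param eig_tol Nonnegative eigenvalue tolerance.
#' @return Logical scalar.
#' @export
is_psd <- function(triple, eig_tol = 1e-10) {
  v <- .triple_values(triple)
  if (any(abs(v) > 1)) stop("correlations must lie in [-1, 1]")
  R <- matrix(c(1, v["rho_xm"], v["rho_xy"],
                v["rho_xm"], 1, v["rho_ym"],
                v["rho_xy"], v["rho_ym"], 1), 3, 3)
  min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) >= -eig_tol
}

.triple_values <- function(triple) {
  if (inherits(triple, "corr_triple")) {
    c(rho_xy = triple$rho_xy, rho_xm = triple$rho_xm, rho_ym = triple$rho_ym)
  } else if (is.numeric(triple) && length(triple) == 3) {
    if (is.null(names(triple))) names(triple) <- c("rho_xy", "rho_xm", "rho_ym")
    triple[c("rho_xy", "rho_xm", "rho_ym")]
  } else {
    stop("expected a corr_triple or a numeric vector (rho_xy, rho_xm, rho_ym)")
  }
}

#' Measurement-error model configuration
#'
#' One point in the generative measurement-error model: a causal structure,
#' the three causal correlations among the error-free variables, and the three
#' error correlations tying each causal variable to its measurement. For the
#' constrained structures the causal correlation between the two non-middle
#' variables equals the product of the other two; it may be omitted and is
#' then filled in by that product.
#'
#' Error correlations must lie in (0, 1]: a value of 1 means the variable is
#' measured without error, while a value of 0 would make the measurement pure
#' noise and all of its data correlations zero, which is rejected.
#'
#' @param structure One of `causal_structures()`.
#' @param rho_xm,rho_xy,rho_ym Causal correlations; for a constrained
#'   structure the constrained one may be `NULL`.
#' @param err_x,err_m,err_y Error correlations in (0, 1]; default 1 (no
#'   measurement error).
#' @param tol Tolerance for the structure product constraint.
#' @return An object of class `"me_config"`.
#' @seealso [implied_data_cor()], [latent_from_config()], [simulate_triplet()]
#' @examples
#' cfg <- me_config("Causal", rho_xm = 0.9, rho_ym = 0.8,
#'                  err_x = 0.9, err_m = 0.8, err_y = 0.9)
#' implied_data_cor(cfg)
#' @export
me_config <- function(structure, rho_xm = NULL, rho_xy = NULL, rho_ym = NULL,
                      err_x = 1, err_m = 1, err_y = 1, tol = 1e-8) {
  structure <- match.arg(structure, causal_structures())
  err <- c(err_x = err_x, err_m = err_m, err_y = err_y)
  if (any(!is.finite(err)) || any(err <= 0) || any(err > 1)) {
    stop("error correlations must lie in (0, 1]: a zero error correlation ",
         "makes a variable pure noise and all its data correlations zero")
  }
  # fill the constrained causal correlation from the product of the free two
  if (structure == "Causal" && is.null(rho_xy)) {
    if (is.null(rho_xm) || is.null(rho_ym)) stop("Causal needs rho_xm, rho_ym")
    rho_xy <- rho_xm * rho_ym
  } else if (structure == "Independent" && is.null(rho_ym)) {
    if (is.null(rho_xm) || is.null(rho_xy)) stop("Independent needs rho_xm, rho_xy")
    rho_ym <- rho_xm * rho_xy
  } else if (structure == "Reactive" && is.null(rho_xm)) {
    if (is.null(rho_xy) || is.null(rho_ym)) stop("Reactive needs rho_xy, rho_ym")
    rho_xm <- rho_xy * rho_ym
  }
  if (is.null(rho_xm) || is.null(rho_xy) || is.null(rho_ym)) {
    stop("all three causal correlations are required for structure ", structure)
  }
  causal <- corr_triple(rho_xy, rho_xm, rho_ym, role = "causal")
  if (structure != "Complex") {
    chk <- structure_constraint(causal, structure, tol = tol)
    if (!chk$ok) {
      stop(sprintf(
        "violated constraint: %s structure requires the non-middle causal correlation to equal the product of the other two (residual %.3g)",
        structure, chk$residual))
    }
  }
  structure(list(structure = structure, causal = causal,
                 err_x = unname(err_x), err_m = unname(err_m),
                 err_y = unname(err_y)),
            class = "me_config")
}

#' @export
print.me_config <- function(x, ...) {
  cat(sprintf("<me_config %s>\n", x$structure))
  cat(sprintf("  causal: rho_xy=%.4g rho_xm=%.4g rho_ym=%.4g\n",
              x$causal$rho_xy, x$causal$rho_xm, x$causal$rho_ym))
  cat(sprintf("  error:  rho_x*x=%.4g rho_m*m=%.4g rho_y*y=%.4g\n",
              x$err_x, x$err_m, x$err_y))
  invisible(x)
}

#' Data correlations implied by a measurement-error configuration
#'
#' Each population correlation among the measured variables is the product of
#' the corresponding causal correlation and the error correlations of the two
#' variables involved:
#' \deqn{\rho_{XY} = \rho_{X^*X}\,\rho_{X^*Y^*}\,\rho_{Y^*Y}}
#' and similarly for XM and YM. Data correlations are therefore never stronger
#' in magnitude than their causal counterparts, with equality exactly when
#' both touching error correlations equal 1.
#'
#' @param config An [me_config()].
#' @return A `corr_triple` with role `"data"`.
#' @export
implied_data_cor <- function(config) {
  stopifnot(inherits(config, "me_config"))
  corr_triple(
    rho_xy = config$err_x * config$causal$rho_xy * config$err_y,
    rho_xm = config$err_x * config$causal$rho_xm * config$err_m,
    rho_ym = config$err_y * config$causal$rho_ym * config$err_m,
    role = "data")
}

#' Check the product constraint of a constrained structure
#'
#' For the Causal, Independent, and Reactive structures the correlation
#' between the two non-middle variables is constrained to equal the product of
#' the other two correlations (equivalently, their partial correlation given
#' the middle variable is zero). Returns whether the constraint holds at
#' tolerance `tol` along with the signed residual
#' (non-middle correlation minus product).
#'
#' @param triple A `corr_triple` (any role) or numeric vector.
#' @param structure A constrained structure (not `"Complex"`).
#' @param tol Nonnegative tolerance. The default suits exact configurations;
#'   use a looser value for estimated triples.
#' @return List with elements `ok` (logical) and `residual` (numeric).
#' @export
structure_constraint <- function(triple, structure, tol = 1e-8) {
  structure <- match.arg(structure, causal_structures())
  if (structure == "Complex") {
    stop("unconstrained structure: Complex imposes no product constraint")
  }
  v <- .triple_values(triple)
  residual <- switch(structure,
    Causal      = v[["rho_xy"]] - v[["rho_xm"]] * v[["rho_ym"]],
    Independent = v[["rho_ym"]] - v[["rho_xm"]] * v[["rho_xy"]],
    Reactive    = v[["rho_xm"]] - v[["rho_xy"]] * v[["rho_ym"]])
  list(ok = abs(residual) <= tol, residual = residual)
}

#' Complex no-error equivalent of a configuration
#'
#' Every measurement-error configuration is likelihood-equivalent to a Complex
#' configuration without measurement error whose causal correlations equal the
#' original configuration's implied data correlations. The returned
#' configuration therefore reproduces the input's data correlations exactly,
#' which is why the causal structure cannot be recovered from the measured
#' variables alone.
#'
#' @param config An [me_config()].
#' @return An `me_config` with structure `"Complex"` and all error
#'   correlations equal to 1. Idempotent for error-free Complex inputs.
#' @export
complex_equivalent <- function(config) {
  d <- implied_data_cor(config)
  me_config("Complex", rho_xm = d$rho_xm, rho_xy = d$rho_xy, rho_ym = d$rho_ym,
            err_x = 1, err_m = 1, err_y = 1)
}

#' Write / read a measurement-error configuration
#'
#' Serializes a configuration to a flat `key = value` text file (structure,
#' three causal correlations, three error correlations) and back.
#'
#' @param config An [me_config()].
#' @param path File path.
#' @return `write_me_config` returns `path` invisibly; `read_me_config`
#'   returns the reconstructed `me_config`.
#' @export
write_me_config <- function(config, path) {
  stopifnot(inherits(config, "me_config"))
  lines <- c(
    paste("structure =", config$structure),
    sprintf("rho_xm = %.17g", config$causal$rho_xm),
    sprintf("rho_xy = %.17g", config$causal$rho_xy),
    sprintf("rho_ym = %.17g", config$causal$rho_ym),
    sprintf("err_x = %.17g", config$err_x),
    sprintf("err_m = %.17g", config$err_m),
    sprintf("err_y = %.17g", config$err_y))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_me_config
#' @export
read_me_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  names(vals) <- keys
  need <- c("structure", "rho_xm", "rho_xy", "rho_ym",
            "err_x", "err_m", "err_y")
  if (!all(need %in% keys)) {
    stop("config file missing keys: ", paste(setdiff(need, keys), collapse = ", "))
  }
  me_config(vals[["structure"]],
            rho_xm = as.numeric(vals[["rho_xm"]]),
            rho_xy = as.numeric(vals[["rho_xy"]]),
            rho_ym = as.numeric(vals[["rho_ym"]]),
            err_x = as.numeric(vals[["err_x"]]),
            err_m = as.numeric(vals[["err_m"]]),
            err_y = as.numeric(vals[["err_y"]]))
}
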