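#' Compaction parameter set
#'
#' Tuning parameters of the two empirical compaction laws used throughout
#' the package: the Kawakita compressibility law
#' `eps(P) = eps0 / (1 + B * P)` (initial powder-bed porosity `eps0`;
#' grouped constant `B = (Vinf/V0) * b`, 1/MPa) and the
#' Ryshkewitch-Duckworth compactability law
#' `sigma(eps) = That * exp(-kb * eps)` (zero-porosity strength `That`,
#' MPa; bonding-capacity constant `kb`). `err_k` and `err_rd` record the
#' root-mean-squared error of each fit.
#'
#' @param eps0 initial powder-bed porosity, in (0, 1).
#' @param B grouped Kawakita constant, 1/MPa, positive.
#' @param That zero-porosity tensile strength, MPa, positive.
#' @param kb bonding capacity, dimensionless, positive.
#' @param err_k,err_rd fit RMSEs (porosity / MPa scale), non-negative.
#' @return object of class `compaction_params`.
#' @export
compaction_params <- function(eps0, B, That, kb, err_k = 0, err_rd = 0) {
  stopifnot(eps0 > 0, eps0 < 1, B > 0, That > 0, kb > 0, err_k >= 0, err_rd >= 0)
  structure(list(eps0 = eps0, B = B, That = That, kb = kb,
                 err_k = err_k, err_rd = err_rd),
            class = "compaction_params")
}

#' @export
print.compaction_params <- function(x, ...) {
  cat(sprintf("<compaction_params> eps0=%.4f B=%.5f 1/MPa | That=%.3f MPa kb=%.3f | RMSE %.2e / %.2e\n",
              x$eps0, x$B, x$That, x$kb, x$err_k, x$err_rd))
  invisible(x)
}

#' Kawakita compressibility law
#'
#' Tablet porosity as a function of main compression pressure:
#' `eps(P) = eps0 / (1 + B * P)`, strictly decreasing in `P`.
#'
#' @param P compression pressure(s), MPa, non-negative.
#' @param p a [compaction_params()] (or any list with `eps0`, `B`).
#' @return porosity fraction(s).
#' @export
kawakita_porosity <- function(P, p) {
  stopifnot(all(P >= 0))
  p$eps0 / (1 + p$B * P)
}

#' Ryshkewitch-Duckworth compactability law
#'
#' Tablet tensile strength as a function of porosity:
#' `sigma(eps) = That * exp(-kb * eps)`, strictly decreasing in `eps`.
#'
#' @param eps porosity fraction(s) in `[0, 1)`.
#' @param p a [compaction_params()] (or any list with `That`, `kb`).
#' @return tensile strength(s), MPa.
#' @export
rd_tensile <- function(eps, p) {
  stopifnot(all(eps >= 0), all(eps < 1))
  p$That * exp(-p$kb * eps)
}

#' Fit the Kawakita law to pressure-porosity data
#'
#' Nonlinear least squares on porosity (bounded Levenberg-Marquardt via
#' \pkg{minpack.lm}), with a closed-form two-point solution used for
#' starting values. Bounds: `eps0` in (0, 1), `B` in (1e-6, 1) 1/MPa.
#'
#' @param P pressures, MPa (at least 2 distinct values).
#' @param eps observed porosities (same length).
#' @return object of class `kawakita_fit` (also a list with `eps0`, `B`,
#'   `err_k`) supporting `coef()`, `print()` and `predict(fit, P)`.
#' @export
fit_kawakita <- function(P, eps) {
  P <- as.numeric(P); eps <- as.numeric(eps)
  stopifnot(length(P) == length(eps))
  if (length(unique(P)) < 2L) {
    stop("fit_kawakita is underdetermined: need at least 2 distinct pressures")
  }
  if (any(eps <= 0) || any(eps >= 1)) stop("porosities must lie in (0, 1)")
  # two-point closed form on the extreme pressures for starting values
  i1 <- which.min(P); i2 <- which.max(P)
  B0 <- (eps[i1] - eps[i2]) / max(eps[i2] * P[i2] - eps[i1] * P[i1], 1e-12)
  B0 <- min(max(B0, 1e-5), 0.9)
  e0 <- min(max(eps[i1] * (1 + B0 * P[i1]), 1e-3), 0.99)
  df <- data.frame(P = P, eps = eps)
  fit <- tryCatch(
    minpack.lm::nlsLM(eps ~ eps0 / (1 + B * P), data = df,
                      start = list(eps0 = e0, B = B0),
                      lower = c(1e-6, 1e-6), upper = c(1 - 1e-9, 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf("Kawakita fit failed to converge: %s", conditionMessage(e))))
  cf <- stats::coef(fit)
  resid <- eps - cf[["eps0"]] / (1 + cf[["B"]] * P)
  structure(list(eps0 = unname(cf[["eps0"]]), B = unname(cf[["B"]]),
                 err_k = sqrt(mean(resid^2)), n = length(P),
                 data = df),
            class = "kawakita_fit")
}

#' @export
coef.kawakita_fit <- function(object, ...) c(eps0 = object$eps0, B = object$B)

#' @export
print.kawakita_fit <- function(x, ...) {
  cat(sprintf("Kawakita fit (n=%d): eps0 = %.4f, B = %.5f 1/MPa, RMSE = %.3e\n",
              x$n, x$eps0, x$B, x$err_k))
  invisible(x)
}

#' @export
predict.kawakita_fit <- function(object, P, ...) kawakita_porosity(P, object)

#' Fit the Ryshkewitch-Duckworth law to porosity-strength data
#'
#' Linear least squares on `log(sigma)` versus porosity (exact for
#' noiseless data and numerically stable), back-transformed to `That` and
#' `kb`; the reported RMSE is computed on the MPa scale.
#'
#' @param eps porosities in `[0, 1)` (at least 2 distinct values).
#' @param sigma tensile strengths, MPa, positive (same length).
#' @return object of class `rd_fit` (fields `That`, `kb`, `err_rd`)
#'   supporting `coef()`, `print()` and `predict(fit, eps)`.
#' @export
fit_rd <- function(eps, sigma) {
  eps <- as.numeric(eps); sigma <- as.numeric(sigma)
  stopifnot(length(eps) == length(sigma))
  if (length(unique(eps)) < 2L) {
    stop("fit_rd is underdetermined: need at least 2 distinct porosities")
  }
  if (any(sigma <= 0)) stop("tensile strengths must be positive")
  fit <- stats::lm(log(sigma) ~ eps)
  cf <- stats::coef(fit)
  That <- exp(unname(cf[1L])); kb <- -unname(cf[2L])
  if (!is.finite(That) || That <= 0 || !is.finite(kb)) {
    stop("Ryshkewitch-Duckworth fit failed: non-finite parameters")
  }
  if (kb <= 0) {
    # strength increasing with porosity: outside the model's validity
    kb <- max(kb, 1e-9)
  }
  resid <- sigma - That * exp(-kb * eps)
  structure(list(That = That, kb = kb, err_rd = sqrt(mean(resid^2)),
                 n = length(eps), data = data.frame(eps = eps, sigma = sigma)),
            class = "rd_fit")
}

#' @export
coef.rd_fit <- function(object, ...) c(That = object$That, kb = object$kb)

#' @export
print.rd_fit <- function(x, ...) {
  cat(sprintf("Ryshkewitch-Duckworth fit (n=%d): That = %.3f MPa, kb = %.3f, RMSE = %.3e MPa\n",
              x$n, x$That, x$kb, x$err_rd))
  invisible(x)
}

#' @export
predict.rd_fit <- function(object, eps, ...) rd_tensile(eps, object)

#' Pressure needed to reach a target porosity
#'
#' Closed-form inversion of the Kawakita law:
#' `P* = (eps0 / eps_target - 1) / B`.
#'
#' @param eps_target target porosity, strictly between 0 and `p$eps0`.
#' @param p a [compaction_params()] or [fit_kawakita()] result.
#' @return pressure, MPa.
#' @export
pressure_for_porosity <- function(eps_target, p) {
  if (eps_target <= 0 || eps_target >= p$eps0) {
    stop(sprintf("target porosity %.4f is infeasible: must lie in (0, eps0=%.4f)",
                 eps_target, p$eps0))
  }
  (p$eps0 / eps_target - 1) / p$B
}

#' Tensile strength interpolated at a reference porosity
#'
#' Fits the Ryshkewitch-Duckworth law to `(eps, sigma)` data and evaluates
#' it at `eps_star` (15% porosity by default, the usual manufacturability
#' reference point).
#'
#' @inheritParams fit_rd
#' @param eps_star reference porosity (default 0.15).
#' @return tensile strength at `eps_star`, MPa.
#' @export
tensile_at_porosity <- function(eps, sigma, eps_star = 0.15) {
  fit <- fit_rd(eps, sigma)
  rd_tensile(eps_star, fit)
}

#' Export a compaction profile
#'
#' Writes the `(P, eps, sigma)` profile as CSV next to a JSON file of the
#' fitted parameters.
#'
#' @param P,eps,sigma profile vectors.
#' @param params a [compaction_params()].
#' @param path CSV output path; the JSON lands at `<path>.params.json`.
#' @return `path`, invisibly.
#' @export
write_compaction_profile <- function(P, eps, sigma, params, path) {
  utils::write.csv(data.frame(P_MPa = P, porosity = eps, tensile_MPa = sigma),
                   path, row.names = FALSE)
  writeLines(jsonlite::toJSON(unclass(params), digits = NA, auto_unbox = TRUE),
             paste0(path, ".params.json"))
  invisible(path)
}
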