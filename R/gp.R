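# Small 1-D Gaussian-process regressor (squared-exponential kernel,
# ML-II hyperparameters, observation-noise floor) used as the PIBO
# surrogate for porosity versus pressure. Inputs are scaled to the unit
# interval and the target is z-scored internally.

gp_fit <- function(x, y, noise_floor = 1e-4) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(n >= 2L, length(y) == n)
  x0 <- min(x); xr <- max(max(x) - x0, 1e-12)
  ym <- mean(y); ys <- max(stats::sd(y), 1e-12)
  xs <- (x - x0) / xr
  yn <- (y - ym) / ys
  # noise floor expressed on the standardised target scale
  floor_s <- (noise_floor / ys)^2

  nll <- function(theta) {
    ell <- exp(theta[1L]); s2 <- exp(theta[2L]); sn2 <- exp(theta[3L]) + floor_s
    K <- s2 * exp(-0.5 * outer(xs, xs, "-")^2 / ell^2) + diag(sn2, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), yn))
    0.5 * sum(yn * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  }
  starts <- list(c(log(0.3), 0, log(max(floor_s, 1e-6))),
                 c(log(1.0), 0, log(max(floor_s, 1e-4))))
  best <- NULL
  for (st in starts) {
    op <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   lower = c(log(0.02), log(1e-4), log(1e-10)),
                   upper = c(log(20), log(100), log(1))),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) best <- list(par = starts[[1L]])
  ell <- exp(best$par[1L]); s2 <- exp(best$par[2L])
  sn2 <- exp(best$par[3L]) + floor_s
  K <- s2 * exp(-0.5 * outer(xs, xs, "-")^2 / ell^2) + diag(sn2, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yn))
  structure(list(xs = xs, alpha = alpha, chol = ch, ell = ell, s2 = s2, sn2 = sn2,
                 x0 = x0, xr = xr, ym = ym, ys = ys, n = n),
            class = "gp1d")
}

gp_predict <- function(gp, xnew) {
  zs <- (as.numeric(xnew) - gp$x0) / gp$xr
  Ks <- gp$s2 * exp(-0.5 * outer(zs, gp$xs, "-")^2 / gp$ell^2)
  mu <- as.numeric(Ks %*% gp$alpha)
  v <- backsolve(gp$chol, forwardsolve(t(gp$chol), t(Ks)))  # K^{-1} Ks'
  var <- pmax(gp$s2 - colSums(v * t(Ks)), 1e-12)            # latent variance
  list(mean = mu * gp$ys + gp$ym, sd = sqrt(var) * gp$ys)
}

# E[(gbest - |Z|)^+] for Z ~ N(m, s^2): expected improvement of the
# absolute deviation from the target porosity below the incumbent gbest.
folded_ei <- function(m, s, gbest) {
  if (gbest <= 0) return(rep(0, length(m)))
  s <- pmax(s, 1e-12)
  u2 <- (gbest - m) / s
  u1 <- (-gbest - m) / s
  u0 <- -m / s
  ip <- function(lo, hi) m * (stats::pnorm(hi) - stats::pnorm(lo)) +
    s * (stats::dnorm(lo) - stats::dnorm(hi))   # integral of z over [lo, hi] (std units)
  e_abs <- (ip(u0, u2)) - (ip(u1, u0))
  pmax(gbest * (stats::pnorm(u2) - stats::pnorm(u1)) - e_abs, 0)
}
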