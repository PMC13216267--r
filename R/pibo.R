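#' PIBO agent configuration
#'
#' @param target_eps target tablet porosity (default 0.15).
#' @param rel_tol termination threshold: relative change of both fit RMSEs
#'   over the last two iterations must fall below it (default 0.20).
#' @param max_iter maximum refinement iterations after initialisation
#'   (default 15).
#' @param n_init number of initial observations (default 2; two points are
#'   the minimum that determines the two-parameter compaction laws).
#' @param init_factor the second initial pressure is `init_factor * P0`
#'   (default 1.25).
#' @param theta_sigma manufacturability floor for the validation tablet,
#'   MPa (default 2).
#' @param grid_n acquisition grid resolution (default 512).
#' @param noise_floor GP observation-noise floor on porosity
#'   (default 1e-4).
#' @return list of class `pibo_config`.
#' @export
pibo_config <- function(target_eps = 0.15, rel_tol = 0.20, max_iter = 15L,
                        n_init = 2L, init_factor = 1.25, theta_sigma = 2,
                        grid_n = 512L, noise_floor = 1e-4) {
  stopifnot(target_eps > 0, target_eps < 1, rel_tol > 0, n_init >= 2L,
            init_factor > 0, init_factor != 1)
  structure(list(target_eps = target_eps, rel_tol = rel_tol,
                 max_iter = as.integer(max_iter), n_init = as.integer(n_init),
                 init_factor = init_factor, theta_sigma = theta_sigma,
                 grid_n = as.integer(grid_n), noise_floor = noise_floor),
            class = "pibo_config")
}

fit_compaction_pair <- function(P, eps, sigma) {
  kf <- tryCatch(fit_kawakita(P, eps), error = function(e) NULL)
  rf <- tryCatch(fit_rd(eps, sigma), error = function(e) NULL)
  if (is.null(kf) || is.null(rf)) return(NULL)
  compaction_params(kf$eps0, kf$B, rf$That, rf$kb,
                    err_k = kf$err_k, err_rd = rf$err_rd)
}

#' Initialise the PIBO experiment loop
#'
#' Takes `n_init` observations (at `P0` and at `init_factor * P0`, clamped
#' into the plant's press bounds), fits the Kawakita and
#' Ryshkewitch-Duckworth laws, and builds the porosity-pressure GP
#' surrogate.
#'
#' @param P0 initial main compression pressure from the digital
#'   formulator, MPa.
#' @param plant a [virtual_plant()].
#' @param config a [pibo_config()].
#' @return object of class `pibo_state`: dataset `D` (`P`, `eps`,
#'   `sigma`), current `params`, `params_history`, `err_history` (one row
#'   per iteration), GP surrogate, `iteration`, `terminated`.
#' @export
pibo_init <- function(P0, plant, config = pibo_config()) {
  stopifnot(inherits(plant, "virtual_plant"))
  bounds <- plant$pressure_bounds
  if (P0 < bounds[1L] || P0 > bounds[2L]) {
    stop(sprintf("P0 = %.1f MPa outside plant bounds [%g, %g]", P0, bounds[1L], bounds[2L]))
  }
  Ps <- clamp(P0 * config$init_factor^(0:(config$n_init - 1L)), bounds[1L], bounds[2L])
  Ps <- unique(Ps)
  if (length(Ps) < 2L) Ps <- c(Ps, clamp(Ps * 0.8, bounds[1L], bounds[2L]))[1:2]
  D <- data.frame(P = numeric(0), eps = numeric(0), sigma = numeric(0))
  for (P in Ps) {
    obs <- observe_accepted(plant, P)
    D <- rbind(D, data.frame(P = obs$P, eps = obs$porosity, sigma = obs$tensile))
  }
  params <- fit_compaction_pair(D$P, D$eps, D$sigma)
  if (is.null(params)) stop("initial compaction fits failed")
  structure(list(D = D, params = params, params_history = list(params),
                 err_history = matrix(c(params$err_k, params$err_rd), nrow = 1L,
                                      dimnames = list(NULL, c("err_k", "err_rd"))),
                 gp = gp_fit(D$P, D$eps, config$noise_floor),
                 bounds = bounds, iteration = 1L, terminated = FALSE,
                 flagged_iterations = integer(0), validation = NULL),
            class = "pibo_state")
}

#' @export
print.pibo_state <- function(x, ...) {
  cat(sprintf("<pibo_state> iteration %d, %d observations, terminated: %s\n",
              x$iteration, nrow(x$D), x$terminated))
  print(x$params)
  invisible(x)
}

# anticipated post-refit RMSEs with a pseudo-observation at P_cand taken
# from the surrogate posterior mean (and the current R-D curve for sigma)
anticipated_errs <- function(state, P_cand) {
  eps_hat <- clamp(gp_predict(state$gp, P_cand)$mean, 1e-3, 0.95)
  sigma_hat <- rd_tensile(eps_hat, state$params)
  kf <- tryCatch(fit_kawakita(c(state$D$P, P_cand), c(state$D$eps, eps_hat)),
                 error = function(e) NULL)
  rf <- tryCatch(fit_rd(c(state$D$eps, eps_hat), c(state$D$sigma, sigma_hat)),
                 error = function(e) NULL)
  if (is.null(kf) || is.null(rf)) return(c(Inf, Inf))
  c(kf$err_k, rf$err_rd)
}

#' Propose the next compression pressure
#'
#' Physics-constrained acquisition: maximises the expected improvement of
#' the GP surrogate's absolute deviation from the target porosity, but a
#' candidate is only acceptable if the *anticipated* post-refit RMSEs of
#' the Kawakita and Ryshkewitch-Duckworth fits (computed by refitting with
#' the surrogate posterior mean at the candidate as a pseudo-observation)
#' do not exceed the current RMSEs — the optimisation trajectory is
#' confined to not degrade the physics fits. When no grid candidate
#' passes, the proposal falls back to the closed-form Kawakita inversion
#' at the target porosity under the current parameters (projected into
#' the press bounds with a warning if necessary).
#'
#' @param state a [pibo_init()] (or updated) state.
#' @param config a [pibo_config()].
#' @return proposed pressure, MPa.
#' @export
propose_pressure <- function(state, config = pibo_config()) {
  stopifnot(inherits(state, "pibo_state"))
  if (state$terminated) stop("PIBO loop already terminated")
  target <- config$target_eps
  grid <- seq(state$bounds[1L], state$bounds[2L], length.out = config$grid_n)
  pr <- gp_predict(state$gp, grid)
  gbest <- min(abs(state$D$eps - target))
  ei <- folded_ei(pr$mean - target, pr$sd, gbest)
  cur <- c(state$params$err_k, state$params$err_rd)
  tol <- 1e-12 + 1e-9 * cur
  for (i in order(ei, decreasing = TRUE)) {
    if (ei[i] <= 0) break
    ant <- anticipated_errs(state, grid[i])
    if (ant[1L] <= cur[1L] + tol[1L] && ant[2L] <= cur[2L] + tol[2L]) {
      return(grid[i])
    }
  }
  # physics-based fallback: invert the current Kawakita fit at the target
  P_star <- tryCatch(pressure_for_porosity(target, state$params),
                     error = function(e) NA_real_)
  if (!is.finite(P_star)) P_star <- mean(state$bounds)
  if (P_star < state$bounds[1L] || P_star > state$bounds[2L]) {
    warning(sprintf("fallback pressure %.1f MPa projected into press bounds", P_star))
    P_star <- clamp(P_star, state$bounds[1L], state$bounds[2L])
  }
  P_star
}

#' Incorporate a new observation
#'
#' Appends the observation, refits both compaction laws, appends the fit
#' RMSEs to the error history and updates the GP surrogate. If a refit
#' fails the previous parameters are kept and the iteration is flagged.
#'
#' @param state a `pibo_state`.
#' @param obs a [observe_tablet()] result (D1-accepted).
#' @param config a [pibo_config()].
#' @return the updated `pibo_state`.
#' @export
pibo_update <- function(state, obs, config = pibo_config()) {
  stopifnot(inherits(state, "pibo_state"))
  if (!isTRUE(obs$accepted_d1)) stop("observation was rejected at gate D1; re-dose first")
  state$D <- rbind(state$D, data.frame(P = obs$P, eps = obs$porosity, sigma = obs$tensile))
  params <- fit_compaction_pair(state$D$P, state$D$eps, state$D$sigma)
  if (is.null(params)) {
    state$flagged_iterations <- c(state$flagged_iterations, state$iteration + 1L)
    params <- state$params
  }
  state$params <- params
  state$params_history <- c(state$params_history, list(params))
  state$err_history <- rbind(state$err_history, c(params$err_k, params$err_rd))
  state$gp <- gp_fit(state$D$P, state$D$eps, config$noise_floor)
  state$iteration <- state$iteration + 1L
  state
}

#' Check the PIBO termination criterion
#'
#' Terminates when the relative change of *both* fit RMSEs over the last
#' two iterations is below `rel_tol` (20% by default). A previous RMSE of
#' exactly zero gives a relative change of 0 if the new RMSE is also zero
#' and infinity otherwise.
#'
#' @param state a `pibo_state` with at least two iterations of history.
#' @param rel_tol relative-change threshold (default 0.20).
#' @return logical.
#' @export
check_termination <- function(state, rel_tol = 0.20) {
  eh <- state$err_history
  if (nrow(eh) < 2L) return(FALSE)
  # errors at numerical-noise level (exact fits) count as zero
  z <- function(e) ifelse(e < 1e-9, 0, e)
  prev <- z(eh[nrow(eh) - 1L, ])
  cur <- z(eh[nrow(eh), ])
  relchange <- ifelse(prev == 0, ifelse(cur == 0, 0, Inf), abs(cur - prev) / prev)
  all(relchange < rel_tol)
}

#' Validation experiment at the target porosity
#'
#' Inverts the calibrated Kawakita law at the target porosity, takes one
#' plant observation at that pressure and scores it against the
#' manufacturability floor.
#'
#' @param state a terminated `pibo_state`.
#' @param plant the [virtual_plant()].
#' @param config a [pibo_config()].
#' @return list: `P_val`, `eps_obs`, `sigma_obs`, `eps_err`
#'   (absolute porosity error), `pass` (`sigma_obs >= theta_sigma`).
#' @export
pibo_validate <- function(state, plant, config = pibo_config()) {
  stopifnot(inherits(state, "pibo_state"))
  P_val <- pressure_for_porosity(config$target_eps, state$params)
  if (P_val < plant$pressure_bounds[1L] || P_val > plant$pressure_bounds[2L]) {
    warning("validation pressure projected into press bounds")
    P_val <- clamp(P_val, plant$pressure_bounds[1L], plant$pressure_bounds[2L])
  }
  obs <- observe_accepted(plant, P_val)
  list(P_val = P_val, eps_obs = obs$porosity, sigma_obs = obs$tensile,
       eps_err = abs(obs$porosity - config$target_eps),
       pass = obs$tensile >= config$theta_sigma)
}

#' Run the full PIBO refinement loop
#'
#' Initialise, then propose/observe/update until the termination criterion
#' fires or `max_iter` refinement iterations are exhausted, followed by
#' the validation experiment.
#'
#' @param P0 initial pressure from the digital formulator, MPa.
#' @param plant a [virtual_plant()].
#' @param config a [pibo_config()].
#' @return object of class `pibo_run`: the final `state`,
#'   `n_experiments` (observations before validation), `validation`,
#'   `converged`, and `trajectories` (per-parameter histories normalised
#'   to `[0, 1]` over the run).
#' @export
run_pibo <- function(P0, plant, config = pibo_config()) {
  state <- pibo_init(P0, plant, config)
  while (!state$terminated && state$iteration - 1L < config$max_iter) {
    P_next <- propose_pressure(state, config)
    obs <- observe_accepted(plant, P_next)
    state <- pibo_update(state, obs, config)
    if (check_termination(state, config$rel_tol)) state$terminated <- TRUE
  }
  converged <- state$terminated
  validation <- pibo_validate(state, plant, config)
  H <- vapply(state$params_history, function(p) c(p$eps0, p$B, p$That, p$kb), numeric(4L))
  traj <- t(apply(H, 1L, function(v) {
    if (max(v) - min(v) < 1e-15) rep(0.5, length(v)) else (v - min(v)) / (max(v) - min(v))
  }))
  rownames(traj) <- c("eps0", "B", "That", "kb")
  structure(list(state = state, n_experiments = nrow(state$D),
                 validation = validation, converged = converged,
                 trajectories = traj, config = config, P0 = P0),
            class = "pibo_run")
}

#' @export
print.pibo_run <- function(x, ...) {
  v <- x$validation
  cat(sprintf("<pibo_run> %d experiments (+1 validation), %s\n",
              x$n_experiments, if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  validation: P = %.1f MPa, porosity %.4f (|err| %.4f), tensile %.2f MPa [%s]\n",
              v$P_val, v$eps_obs, v$eps_err, v$sigma_obs, if (v$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Plot a PIBO run
#'
#' Two base-graphics panels: the collected compressibility data with the
#' calibrated Kawakita curve, and the normalised parameter trajectories
#' over iterations.
#'
#' @param x a [run_pibo()] result.
#' @param ... passed to `plot`.
#' @export
plot.pibo_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  D <- x$state$D
  Pg <- seq(min(D$P) * 0.7, max(D$P) * 1.2, length.out = 200)
  plot(D$P, D$eps, xlab = "pressure (MPa)", ylab = "porosity",
       main = "compressibility", pch = 19, ...)
  graphics::lines(Pg, kawakita_porosity(Pg, x$state$params), col = "steelblue")
  graphics::abline(h = x$config$target_eps, lty = 2, col = "grey40")
  tr <- x$trajectories
  graphics::matplot(seq_len(ncol(tr)), t(tr), type = "b", pch = 1:4, lty = 1,
                    xlab = "iteration", ylab = "normalised parameter",
                    main = "parameter trajectories", ylim = c(0, 1))
  graphics::legend("topright", rownames(tr), col = 1:4, pch = 1:4, cex = 0.8, bty = "n")
  invisible(x)
}

#' Export a PIBO run report as JSON (with a CSV of the dataset)
#'
#' @param run a [run_pibo()] result.
#' @param path JSON output path; the dataset CSV lands at `<path>.csv`.
#' @return `path`, invisibly.
#' @export
write_pibo_report <- function(run, path) {
  st <- run$state
  rep <- list(P0 = run$P0, n_experiments = run$n_experiments,
              converged = run$converged,
              err_history = as.data.frame(st$err_history),
              params = unclass(st$params),
              trajectories = run$trajectories,
              flagged_iterations = st$flagged_iterations,
              validation = run$validation)
  writeLines(jsonlite::toJSON(rep, digits = NA, auto_unbox = TRUE, null = "null"), path)
  utils::write.csv(st$D, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}
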