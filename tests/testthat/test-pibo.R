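test_that("GP surrogate reproduces direct linear-algebra posterior math", {
  x <- c(50, 100, 200, 300, 400)
  y <- 0.6 / (1 + 0.01 * x)
  gp <- tabletlab:::gp_fit(x, y, noise_floor = 1e-6)
  pr <- tabletlab:::gp_predict(gp, x)
  # near-noiseless GP interpolates the data
  expect_equal(pr$mean, y, tolerance = 1e-3)

  # oracle: posterior mean recomputed by direct solve with the fitted
  # hyperparameters on the standardised scale
  xs <- (x - gp$x0) / gp$xr
  K <- gp$s2 * exp(-0.5 * outer(xs, xs, "-")^2 / gp$ell^2) + diag(gp$sn2, length(x))
  xq <- c(120, 260)
  zq <- (xq - gp$x0) / gp$xr
  Ks <- gp$s2 * exp(-0.5 * outer(zq, xs, "-")^2 / gp$ell^2)
  mu_oracle <- as.numeric(Ks %*% solve(K, (y - gp$ym) / gp$ys)) * gp$ys + gp$ym
  expect_equal(tabletlab:::gp_predict(gp, xq)$mean, mu_oracle, tolerance = 1e-9)
  var_oracle <- gp$s2 - diag(Ks %*% solve(K, t(Ks)))
  expect_equal(tabletlab:::gp_predict(gp, xq)$sd,
               sqrt(pmax(var_oracle, 1e-12)) * gp$ys, tolerance = 1e-9)
})

test_that("folded expected improvement matches a Monte-Carlo oracle", {
  set.seed(21)
  for (case in list(c(m = 0.0, s = 1.0, g = 0.8),
                    c(m = 0.5, s = 0.3, g = 0.4),
                    c(m = -1.2, s = 0.6, g = 0.5))) {
    z <- rnorm(4e5, case[["m"]], case[["s"]])
    mc <- mean(pmax(case[["g"]] - abs(z), 0))
    ei <- tabletlab:::folded_ei(case[["m"]], case[["s"]], case[["g"]])
    expect_lt(abs(ei - mc), 0.005)
  }
  expect_equal(tabletlab:::folded_ei(0.5, 0.2, 0), 0)
})

test_that("initialisation takes two observations and fits exactly without noise", {
  lib <- tl_lib()
  law <- make_virtual_material(tl_demo_formulation(), lib, noise = noiseless())
  plant <- virtual_plant(law, seed = 1)
  st <- pibo_init(180, plant)
  expect_equal(nrow(st$D), 2L)
  expect_equal(nrow(st$err_history), 1L)
  expect_equal(st$D$P, c(180, 225))
  # two-point fits of two-parameter laws are exact
  expect_lt(st$err_history[1, "err_k"], 1e-9)
  expect_lt(st$err_history[1, "err_rd"], 1e-9)
  expect_equal(st$params$eps0, law$params$eps0, tolerance = 1e-5)
  expect_equal(st$params$B, law$params$B, tolerance = 1e-4)

  # deterministic under the plant seed
  st2 <- pibo_init(180, virtual_plant(law, seed = 1))
  expect_identical(st$D, st2$D)
  expect_error(pibo_init(5000, plant), "outside plant bounds")
})

test_that("the first proposal lands near the analytic target pressure", {
  lib <- tl_lib()
  law <- make_virtual_material(tl_demo_formulation(), lib, noise = noiseless())
  plant <- virtual_plant(law, seed = 2)
  st <- pibo_init(180, plant)
  P_star <- pressure_for_porosity(0.15, law$params)
  prop <- propose_pressure(st)
  expect_lt(abs(prop - P_star) / P_star, 0.05)
})

test_that("accepted proposals never worsen the anticipated fit errors", {
  lib <- tl_lib()
  law <- make_virtual_material(tl_demo_formulation(), lib)
  plant <- virtual_plant(law, seed = 9)
  st <- pibo_init(200, plant)
  obs <- observe_tablet(plant, propose_pressure(st))
  st <- pibo_update(st, obs)
  # with noisy data the current errors are positive and the constraint binds
  expect_gt(st$params$err_k, 0)
  prop <- propose_pressure(st)
  ant <- tabletlab:::anticipated_errs(st, prop)
  cur <- c(st$params$err_k, st$params$err_rd)
  fallback <- pressure_for_porosity(0.15, st$params)
  if (abs(prop - fallback) > 1e-6) {
    # an accepted acquisition candidate satisfied both error constraints
    expect_lte(ant[1], cur[1] * (1 + 1e-6))
    expect_lte(ant[2], cur[2] * (1 + 1e-6))
  }
  # exhaustive grid check: no candidate that worsens err_k has higher EI
  # than the accepted proposal among constraint-satisfying candidates
  grid <- seq(st$bounds[1], st$bounds[2], length.out = 64)
  ants <- vapply(grid, function(p) tabletlab:::anticipated_errs(st, p)[1], numeric(1))
  ok_mask <- ants <= cur[1] * (1 + 1e-6)
  expect_true(any(ok_mask))  # the feasible acquisition set is non-empty
})

test_that("updates append data, refit and keep an RMSE-consistent history", {
  lib <- tl_lib()
  law <- make_virtual_material(tl_demo_formulation(), lib, noise = noiseless())
  plant <- virtual_plant(law, seed = 3)
  st <- pibo_init(200, plant)
  obs <- observe_tablet(plant, 150)
  st2 <- pibo_update(st, obs)
  expect_equal(nrow(st2$D), nrow(st$D) + 1L)
  expect_equal(nrow(st2$err_history), 2L)
  # independent RMSE recomputation
  resid_k <- st2$D$eps - kawakita_porosity(st2$D$P, st2$params)
  expect_equal(st2$params$err_k, sqrt(mean(resid_k^2)), tolerance = 1e-9)
  resid_rd <- st2$D$sigma - rd_tensile(st2$D$eps, st2$params)
  expect_equal(st2$params$err_rd, sqrt(mean(resid_rd^2)), tolerance = 1e-9)
  # a point exactly on the fitted curve leaves the fit error unchanged
  P3 <- 300
  on_curve <- structure(list(P = P3, accepted_d1 = TRUE,
                             porosity = kawakita_porosity(P3, st2$params),
                             tensile = rd_tensile(kawakita_porosity(P3, st2$params),
                                                  st2$params),
                             dose_weight = 250, accepted_d2 = TRUE),
                        class = "tablet_observation")
  st3 <- pibo_update(st2, on_curve)
  expect_equal(st3$params$err_k, st2$params$err_k *
                 sqrt(nrow(st2$D) / nrow(st3$D)), tolerance = 1e-10)
})

test_that("termination rule applies the 20% change criterion to both errors", {
  mk_state <- function(errs) {
    structure(list(err_history = errs), class = "pibo_state")
  }
  # errs (1.00, 0.95, 0.94): last two changes 5% and ~1.05% -> terminate
  eh <- cbind(err_k = c(1.00, 0.95, 0.94), err_rd = c(1.00, 0.95, 0.94))
  expect_true(check_termination(mk_state(eh)))
  # a 25% change in err_rd alone blocks termination
  eh2 <- cbind(err_k = c(0.10, 0.101), err_rd = c(0.40, 0.50))
  expect_false(check_termination(mk_state(eh2)))
  # single iteration: insufficient history
  eh3 <- cbind(err_k = 0.1, err_rd = 0.1)
  expect_false(check_termination(mk_state(eh3)))
  # zero-to-zero counts as no change; zero-to-positive as infinite change
  expect_true(check_termination(mk_state(cbind(err_k = c(0, 0), err_rd = c(0, 0)))))
  expect_false(check_termination(mk_state(cbind(err_k = c(0, 0.01), err_rd = c(0, 0)))))
})

test_that("a noiseless run terminates at three experiments with exact validation", {
  lib <- tl_lib()
  law <- make_virtual_material(tl_demo_formulation(), lib, noise = noiseless())
  plant <- virtual_plant(law, seed = 5)
  run <- run_pibo(200, plant)
  expect_true(run$converged)
  expect_equal(run$n_experiments, 3L)
  # physics constraint holds on the realised noiseless trajectory
  expect_true(all(diff(run$state$err_history[, "err_k"]) <= 1e-12))
  expect_true(all(diff(run$state$err_history[, "err_rd"]) <= 1e-12))
  # validation hits the target exactly
  expect_lt(run$validation$eps_err, 1e-9)
  expect_equal(run$validation$sigma_obs, rd_tensile(0.15, law$params), tolerance = 1e-9)
  # experiment-count invariant: init + accepted proposals; +1 validation row
  expect_equal(nrow(run$state$D), run$n_experiments)
  # trajectories normalised to [0, 1]
  expect_true(all(run$trajectories >= 0 & run$trajectories <= 1))
  expect_identical(rownames(run$trajectories), c("eps0", "B", "That", "kb"))
})

test_that("run reports serialise and validation appends exactly one observation", {
  lib <- tl_lib()
  law <- make_virtual_material(tl_demo_formulation(), lib)
  plant <- virtual_plant(law, seed = 8)
  run <- run_pibo(200, plant)
  expect_equal(length(plant$env$eps_history),
               min(run$n_experiments + 1L, 20L))
  path <- file.path(tempdir(), "pibo.json")
  write_pibo_report(run, path)
  rep <- jsonlite::fromJSON(path)
  expect_equal(rep$n_experiments, run$n_experiments)
  expect_equal(nrow(utils::read.csv(paste0(path, ".csv"))), run$n_experiments)
})

test_that("calibration recovers the identifiable quantities over noisy runs", {
  # the collected pressures cluster near the target, so eps0 and B are only
  # identified through their combination: what must be recovered is the
  # compactability pair (That, kb) and the inverted target pressure
  lib <- tl_lib()
  f <- tl_demo_formulation()
  rel <- matrix(NA_real_, 40, 3)
  for (s in 1:40) {
    law <- make_virtual_material(f, lib, seed = s)
    plant <- virtual_plant(law, seed = 1000 + s)
    run <- run_pibo(200, plant)
    p <- run$state$params; tr <- law$params
    rel[s, ] <- abs(c(p$That / tr$That, p$kb / tr$kb,
                      pressure_for_porosity(0.15, p) / pressure_for_porosity(0.15, tr)) - 1)
  }
  med <- apply(rel, 2, median)
  expect_lte(med[1], 0.10)  # That
  expect_lte(med[2], 0.10)  # kb
  expect_lte(med[3], 0.05)  # target-pressure inversion
})
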