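#' Noise model of the virtual plant
#'
#' Measurement/process noise applied to virtual tablet observations:
#' additive porosity noise, multiplicative tensile-strength noise and
#' relative dose-weight noise. The defaults echo the weight variability of
#' automated single-tablet manufacture (dose relative standard deviation a
#' few percent).
#'
#' @param porosity_sd additive porosity standard deviation (default 0.005).
#' @param tensile_rel_sd multiplicative tensile noise (default 0.05).
#' @param dose_rel_sd relative dose-weight noise (default 0.02).
#' @return list of class `plant_noise`.
#' @export
plant_noise <- function(porosity_sd = 0.005, tensile_rel_sd = 0.05, dose_rel_sd = 0.02) {
  stopifnot(porosity_sd >= 0, tensile_rel_sd >= 0, dose_rel_sd >= 0)
  structure(list(porosity_sd = porosity_sd, tensile_rel_sd = tensile_rel_sd,
                 dose_rel_sd = dose_rel_sd), class = "plant_noise")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# --- ground-truth rules -----------------------------------------------------
#
# The virtual plant's compaction laws and flow rule are explicit smooth
# functions of blend properties. They are the test oracle of the package,
# not a scientific claim; the functional forms are chosen to reproduce the
# qualitative physics: powder-bed porosity from the bulk/true density
# ratio, easier densification for coarser blends, bonding strength from
# plastic deformability (Carr index) for excipients and from the first
# particle-informatics descriptor for APIs, finer particles bonding into
# stronger compacts, and flow degrading with the fine fraction.

gt_component_strength <- function(rec) {
  if (rec$role == "api") {
    s <- 2 + 6 * stats::plogis(rec$descriptors[1L])
  } else {
    carr <- 1 - rec$bulk_density / rec$tapped_density
    s <- clamp(-2 + 60 * carr, 2, 16)
  }
  d50 <- summarize_psd(rec$psd, warn = FALSE)$d50
  s * (d50 / 60)^(-0.12)
}

gt_component_kb <- function(rec) {
  # plastic (high-Carr) materials keep bonding at higher porosity (low kb);
  # brittle free-flowing ones lose strength quickly with porosity
  carr <- 1 - rec$bulk_density / rec$tapped_density
  clamp(14 - 25 * carr, 5, 13)
}

#' Ground-truth flow function coefficient of the virtual plant
#'
#' The documented flow oracle: FFC (at 1.6 kPa) decays exponentially with
#' the blend's fine fraction below 30 um and degrades mildly with the
#' blend Carr index. Strictly decreasing in the fine fraction; clipped to
#' stay above 1.
#'
#' @param f a [formulation()].
#' @param lib a [material_library()].
#' @return positive FFC value.
#' @export
ground_truth_ffc <- function(f, lib) {
  feats <- ffc_blend_features(f, lib)
  ffc <- 0.8 + 12.5 * exp(-7 * feats[["fines30"]]) - 3 * (feats[["carr"]] - 0.15)
  max(ffc, 1.05)
}

#' Ground-truth compaction law for a formulation
#'
#' Generates the virtual plant's Kawakita and Ryshkewitch-Duckworth
#' parameters for a blend from its mixed properties by a fixed smooth rule
#' (see the package vignette): `eps0` is the powder-bed porosity
#' `1 - rho_bulk/rho_true`; `B` grows with blend median size; `That` is the
#' mass-weighted mixture of per-component bonding strengths (descriptor-
#' driven for the API, Carr-index-driven for excipients, finer particles
#' stronger); `kb` the mass-weighted mixture of per-component bonding
#' capacities. A nonzero `seed` applies a small deterministic log-normal
#' jitter (2%) to emulate batch-to-batch variability.
#'
#' @inheritParams ground_truth_ffc
#' @param seed integer; 0 (default) for the unjittered law.
#' @param noise a [plant_noise()] carried along for the plant.
#' @return object of class `virtual_material_law` holding `params`
#'   ([compaction_params()]), `ffc_true` and `noise`.
#' @export
make_virtual_material <- function(f, lib, seed = 0L, noise = plant_noise()) {
  check_components(f, lib)
  bt <- mix_bulk_tapped(f, lib)
  eps0 <- clamp(1 - bt[["bulk"]] / mix_true_density(f, lib), 0.25, 0.78)
  q <- summarize_psd(mix_distribution(f, lib, "psd"), warn = FALSE)
  B <- 0.004 + 0.028 * stats::plogis((log(q$d50) - log(40)) / 0.9)
  That <- 0; kb <- 0
  for (i in seq_along(f$ids)) {
    rec <- lib_get(lib, f$ids[i])
    That <- That + f$w[i] * gt_component_strength(rec)
    kb <- kb + f$w[i] * gt_component_kb(rec)
  }
  if (seed != 0L) {
    jit <- local({
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed %% 2147483647L)
      exp(stats::rnorm(4L, 0, 0.02))
    })
    eps0 <- clamp(eps0 * jit[1L], 0.05, 0.95)
    B <- B * jit[2L]; That <- That * jit[3L]; kb <- kb * jit[4L]
  }
  structure(list(params = compaction_params(eps0, B, That, kb),
                 ffc_true = ground_truth_ffc(f, lib),
                 formulation = f, noise = noise),
            class = "virtual_material_law")
}

#' @export
print.virtual_material_law <- function(x, ...) {
  cat("<virtual_material_law> FFC", sprintf("%.2f;", x$ffc_true), "")
  print(x$params)
  invisible(x)
}

# --- plant ------------------------------------------------------------------

#' Virtual tableting plant
#'
#' A stateful stand-in for the make-and-test hardware: draws noisy tablet
#' observations from a [make_virtual_material()] law, applies the dose
#' decision gate D1 (reject doses deviating more than 5% from target) and
#' the quality gate D2 (porosity and tensile within 5% of the rolling
#' batch means), and keeps its own random-number stream so plant draws are
#' reproducible regardless of surrounding code.
#'
#' @param law a `virtual_material_law`.
#' @param seed integer seed for the plant's private RNG stream.
#' @param target_weight target dose weight, mg (default 250; 9 mm round
#'   die metadata).
#' @param pressure_bounds admissible press pressures, MPa.
#' @return object of class `virtual_plant`.
#' @export
virtual_plant <- function(law, seed = 1L, target_weight = 250,
                          pressure_bounds = c(10, 500)) {
  stopifnot(inherits(law, "virtual_material_law"))
  env <- new.env(parent = emptyenv())
  local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed %% 2147483647L)
    env$rng_state <- get(".Random.seed", .GlobalEnv)
  })
  env$eps_history <- numeric(0)
  env$sigma_history <- numeric(0)
  structure(list(law = law, env = env, seed = as.integer(seed),
                 target_weight = target_weight,
                 pressure_bounds = pressure_bounds),
            class = "virtual_plant")
}

# run expr with the plant's private RNG stream swapped in
with_plant_rng <- function(plant, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  assign(".Random.seed", plant$env$rng_state, .GlobalEnv)
  on.exit({
    plant$env$rng_state <- get(".Random.seed", .GlobalEnv)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
      rm(".Random.seed", envir = .GlobalEnv)
  })
  force(expr)
}

#' Make and test one virtual tablet
#'
#' Draws a dose, applies gate D1 (within 5% of target weight); if
#' accepted, produces porosity from the Kawakita ground truth plus additive
#' noise (clipped to (0.01, 0.95)) and tensile strength from the
#' Ryshkewitch-Duckworth ground truth at the *observed* porosity with
#' multiplicative noise, then applies gate D2 against the rolling batch
#' means (trivially accepted for the first tablet).
#'
#' @param plant a [virtual_plant()].
#' @param P main compression pressure, MPa, inside the plant's bounds.
#' @return list of class `tablet_observation`: `P`, `dose_weight`,
#'   `accepted_d1`, and when D1 passes `porosity`, `tensile`, `accepted_d2`.
#' @export
observe_tablet <- function(plant, P) {
  stopifnot(inherits(plant, "virtual_plant"))
  if (P < plant$pressure_bounds[1L] || P > plant$pressure_bounds[2L]) {
    stop(sprintf("pressure %.1f MPa outside press bounds [%g, %g]",
                 P, plant$pressure_bounds[1L], plant$pressure_bounds[2L]))
  }
  law <- plant$law
  nz <- law$noise
  draws <- with_plant_rng(plant, stats::rnorm(3L))
  dose <- plant$target_weight * (1 + nz$dose_rel_sd * draws[1L])
  d1 <- abs(dose - plant$target_weight) / plant$target_weight <= 0.05
  obs <- list(P = P, dose_weight = dose, accepted_d1 = d1,
              porosity = NA_real_, tensile = NA_real_, accepted_d2 = NA)
  if (d1) {
    eps <- clamp(kawakita_porosity(P, law$params) + nz$porosity_sd * draws[2L],
                 0.01, 0.95)
    sig <- rd_tensile(eps, law$params) * (1 + nz$tensile_rel_sd * draws[3L])
    sig <- max(sig, 1e-6)
    env <- plant$env
    within5 <- function(x, ref) length(ref) == 0L || abs(x - mean(ref)) <= 0.05 * mean(ref)
    d2 <- within5(eps, env$eps_history) && within5(sig, env$sigma_history)
    env$eps_history <- utils::tail(c(env$eps_history, eps), 20L)
    env$sigma_history <- utils::tail(c(env$sigma_history, sig), 20L)
    obs$porosity <- eps; obs$tensile <- sig; obs$accepted_d2 <- d2
  }
  structure(obs, class = "tablet_observation")
}

# observe until D1 accepts (rejected doses are recycled, not experiments)
observe_accepted <- function(plant, P, max_tries = 25L) {
  for (i in seq_len(max_tries)) {
    obs <- observe_tablet(plant, P)
    if (obs$accepted_d1) return(obs)
  }
  stop("plant failed to produce an accepted dose after 25 tries")
}

# --- synthetic material library --------------------------------------------

synthetic_psd <- function(d50, spread, grid) {
  lognormal_psd(psd_spec("unimodal", d50, spread), grid)
}

synthetic_ard <- function(mean_ar, conc, grid) {
  # beta-shaped aspect-ratio density on (0, 1]
  edges <- as.numeric(grid)
  a <- mean_ar * conc; b <- (1 - mean_ar) * conc
  masses <- diff(stats::pbeta(edges, a, b))
  dist_from_masses(edges, masses / sum(masses))
}

#' Synthetic material library
#'
#' A bundled, fully synthetic library of direct-compression materials:
#' six filler/binders (microcrystalline-cellulose-, lactose- and
#' mannitol-like), one disintegrant, one lubricant and five APIs with
#' seeded particle-informatics descriptors. Densities, particle sizes and
#' flow behaviour are typical textbook values for the material classes;
#' every record's `ffc_measured` is the ground-truth flow rule evaluated
#' on the pure material, so the library is self-consistent with the
#' virtual plant.
#'
#' @param seed seed for the API descriptor draws (default 1).
#' @return a [material_library()].
#' @export
synthetic_material_library <- function(seed = 1L) {
  g <- default_size_grid()
  ga <- default_aspect_grid()
  spec <- list(
    #           role            true  bulk  tapped d50  sg   ar   conc
    MCC_A  = list("filler_binder", 1.56, 0.32, 0.42, 110, 2.0, 0.45, 8),
    MCC_B  = list("filler_binder", 1.56, 0.30, 0.40,  65, 1.9, 0.45, 8),
    MCC_C  = list("filler_binder", 1.55, 0.34, 0.45,  50, 2.1, 0.50, 8),
    LAC_A  = list("filler_binder", 1.54, 0.59, 0.70, 110, 1.8, 0.70, 12),
    LAC_B  = list("filler_binder", 1.54, 0.55, 0.72,  35, 2.2, 0.70, 12),
    MAN_A  = list("filler_binder", 1.49, 0.45, 0.55, 160, 1.7, 0.75, 12),
    CCS_SYN  = list("disintegrant", 1.59, 0.45, 0.60,  45, 1.9, 0.60, 10),
    MGST_SYN = list("lubricant",    1.05, 0.16, 0.26,  10, 1.8, 0.30, 6))
  # 16 synthetic API grades (a realistic library breadth for training
  # material-agnostic models), drawn deterministically under `seed`:
  # scrambled grids spread the bonding-propensity and size axes, and the
  # particle-informatics descriptors are smooth functions of the latent
  # material axes (bonding, density, size, compressibility) plus a small
  # idiosyncratic component — crystallographic descriptors correlate with
  # mechanics rather than encode identity.
  n_api <- 16L
  api_tab <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    bond <- sample(seq(-1.7, 1.3, length.out = n_api))
    d50 <- exp(sample(seq(log(10), log(140), length.out = n_api)))
    true_d <- stats::runif(n_api, 1.22, 1.50)
    carr <- stats::runif(n_api, 0.24, 0.38)
    bulk <- true_d * stats::runif(n_api, 0.18, 0.30)
    tapped <- bulk / (1 - carr)
    sg <- stats::runif(n_api, 1.7, 2.3)
    ar <- stats::runif(n_api, 0.35, 0.65)
    lat <- cbind(bond = bond, dens = (true_d - 1.35) / 0.1,
                 size = (log(d50) - log(50)) / 1, carr = (carr - 0.3) * 20)
    mix <- matrix(c(1, 0, 0, 0,   0, 1, 0, 0,   0, 0, 1, 0,   0, 0, 0, 1,
                    0.7, 0.3, 0, 0,  0.5, 0, -0.5, 0,  0, 0.6, 0.4, 0,
                    -0.4, 0, 0, 0.6,  0.3, -0.3, 0.3, 0.3),
                  nrow = 4L)
    desc <- lat %*% mix + 0.3 * matrix(stats::rnorm(9L * n_api), nrow = n_api)
    desc[, 1L] <- bond  # descriptor 1 is the bonding-propensity axis itself
    list(bond = bond, d50 = d50, true_d = true_d, bulk = bulk, tapped = tapped,
         sg = sg, ar = ar, desc = desc)
  })
  recs <- list()
  for (nm in names(spec)) {
    s <- spec[[nm]]
    recs[[nm]] <- material_record(nm, s[[1L]], s[[2L]], s[[3L]], s[[4L]],
                                  psd = synthetic_psd(s[[5L]], s[[6L]], g),
                                  ard = synthetic_ard(s[[7L]], s[[8L]], ga))
  }
  for (i in seq_len(n_api)) {
    nm <- paste0("API_", LETTERS[i])
    recs[[nm]] <- material_record(nm, "api", api_tab$true_d[i], api_tab$bulk[i],
                                  api_tab$tapped[i],
                                  psd = synthetic_psd(api_tab$d50[i], api_tab$sg[i], g),
                                  ard = synthetic_ard(api_tab$ar[i], 7, ga),
                                  descriptors = api_tab$desc[i, ])
  }
  lib <- material_library(recs)
  # anchor ffc_measured to the ground-truth flow rule on the pure material
  recs <- lapply(lib, function(rec) {
    f <- formulation(rec$id, 1, if (rec$role == "api") rec$id else NULL)
    rec$ffc_measured <- ground_truth_ffc(f, lib)
    rec
  })
  material_library(recs)
}

# --- training corpus --------------------------------------------------------

#' Generate a synthetic tableting training corpus
#'
#' Draws random formulations (APIs at uniform loadings plus a share of
#' placebos, two random filler/binders with a random split, fixed
#' disintegrant and lubricant), observes each at every pressure through a
#' noisy virtual plant, fits the PCA bases for the particle-size and
#' aspect-ratio distributions on the training blends, and assembles the
#' 21-dimensional feature records used by the process models.
#'
#' @param lib a [material_library()] with at least 2 filler/binders and
#'   1 API.
#' @param n_formulations number of random formulations.
#' @param pressures pressure grid, MPa.
#' @param seed integer seed (corpus regenerates bit-identically).
#' @param noise a [plant_noise()]; use zeros for a noiseless corpus.
#' @param placebo_frac share of placebo formulations (default 0.15).
#' @return object of class `tablet_corpus`: `records` (list of
#'   `tablet_record`), `psd_basis`, `ard_basis`, `formulations`.
#' @export
generate_training_corpus <- function(lib, n_formulations, pressures,
                                     seed = 1L, noise = plant_noise(),
                                     placebo_frac = 0.15) {
  apis <- names(lib)[vapply(lib, function(r) r$role == "api", logical(1))]
  fbs <- names(lib)[vapply(lib, function(r) r$role == "filler_binder", logical(1))]
  if (length(fbs) < 2L || length(apis) < 1L) {
    stop("library needs at least 2 filler/binders and 1 API")
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  forms <- vector("list", n_formulations)
  for (i in seq_len(n_formulations)) {
    placebo <- stats::runif(1) < placebo_frac
    api <- if (placebo) NULL else sample(apis, 1L)
    loading <- if (placebo) 0 else stats::runif(1, 0.05, 0.6)
    exc <- sample(fbs, 2L)
    split <- stats::runif(1, 0.1, 0.9)
    forms[[i]] <- make_formulation(api, loading,
                                   stats::setNames(c(split, 1 - split), exc))
  }
  blends <- lapply(forms, function(f) {
    list(psd = mix_distribution(f, lib, "psd"),
         ard = mix_distribution(f, lib, "ard"))
  })
  psd_basis <- fit_distribution_pca(lapply(blends, `[[`, "psd"), 3L)
  ard_basis <- fit_distribution_pca(lapply(blends, `[[`, "ard"), 3L)

  records <- list()
  k <- 0L
  for (i in seq_len(n_formulations)) {
    f <- forms[[i]]
    law <- make_virtual_material(f, lib, seed = 0L, noise = noise)
    plant <- virtual_plant(law, seed = seed + 13L * i)
    api_rec <- if (!is.null(f$api_id)) lib_get(lib, f$api_id) else NULL
    bl <- blend_properties(f, lib)
    bl$ffc <- law$ffc_true
    for (P in pressures) {
      obs <- observe_accepted(plant, P)
      x <- assemble_features(bl, f, api_rec, P, psd_basis, ard_basis)
      k <- k + 1L
      records[[k]] <- structure(
        list(formulation_id = sprintf("F%04d", i), features = x,
             porosity = obs$porosity, tensile = obs$tensile,
             api_id = if (is.null(f$api_id)) "placebo" else f$api_id),
        class = "tablet_record")
    }
  }
  structure(list(records = records, psd_basis = psd_basis, ard_basis = ard_basis,
                 formulations = forms, seed = as.integer(seed)),
            class = "tablet_corpus")
}

#' @export
print.tablet_corpus <- function(x, ...) {
  apis <- table(vapply(x$records, `[[`, character(1), "api_id"))
  cat(sprintf("<tablet_corpus> %d records from %d formulations (%s)\n",
              length(x$records), length(x$formulations),
              paste(sprintf("%s:%d", names(apis), apis), collapse = ", ")))
  invisible(x)
}

#' Export a corpus as CSV
#'
#' @param corpus a [generate_training_corpus()] result.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_corpus_csv <- function(corpus, path) {
  X <- t(vapply(corpus$records, `[[`, numeric(21L), "features"))
  df <- data.frame(
    formulation_id = vapply(corpus$records, `[[`, character(1), "formulation_id"),
    api_id = vapply(corpus$records, `[[`, character(1), "api_id"),
    porosity = vapply(corpus$records, `[[`, numeric(1), "porosity"),
    tensile = vapply(corpus$records, `[[`, numeric(1), "tensile"))
  utils::write.csv(cbind(df, as.data.frame(X)), path, row.names = FALSE)
  invisible(path)
}

# --- simulated NIR spectra and homogeneity monitoring -----------------------

# deterministic per-material band template from the id string
material_band_template <- function(id, n_channels) {
  h <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)) * 131)
  centres <- ((h * c(17, 41, 89)) %% 997) / 997 * (n_channels - 1) + 1
  widths <- n_channels * (0.03 + ((h * c(7, 29, 53)) %% 101) / 101 * 0.07)
  amps <- 0.4 + ((h * c(11, 23, 67)) %% 103) / 103
  ch <- seq_len(n_channels)
  tpl <- rep(0, n_channels)
  for (j in 1:3) tpl <- tpl + amps[j] * exp(-((ch - centres[j]) / widths[j])^2 / 2)
  tpl
}

#' Simulate NIR-like blend spectra
#'
#' Spectra are component-weighted sums of deterministic Gaussian band
#' templates (one template per material id) plus i.i.d. Gaussian channel
#' noise. Each sub-sample's component weights fluctuate slightly
#' (`weight_rel_sd`, relative), emulating the sampling variability of a
#' homogeneous blend — this low-dimensional structured variance is what
#' the PCA model of [hotelling_t2()] captures. Contaminated samples have
#' a fraction of the first component's band weight shifted to the second
#' component, emulating local segregation.
#'
#' @param f a [formulation()].
#' @param lib a [material_library()].
#' @param n number of spectra.
#' @param n_channels spectral channels (default 128).
#' @param noise_sd channel noise standard deviation (default 0.002).
#' @param weight_rel_sd relative sub-sample weight fluctuation
#'   (default 0.02; 0 for perfectly identical sub-samples).
#' @param contamination integer indices of contaminated samples (or NULL).
#' @param contamination_strength fraction of band weight shifted
#'   (default 0.05).
#' @param seed RNG seed.
#' @return numeric matrix `n x n_channels`.
#' @export
simulate_spectra <- function(f, lib, n, n_channels = 128L, noise_sd = 0.002,
                             weight_rel_sd = 0.02,
                             contamination = NULL, contamination_strength = 0.05,
                             seed = 1L) {
  stopifnot(n >= 1L, length(f$ids) >= 1L)
  check_components(f, lib)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  templates <- vapply(f$ids, material_band_template, numeric(n_channels), n_channels)
  out <- matrix(0, n, n_channels)
  for (i in seq_len(n)) {
    w <- f$w
    if (weight_rel_sd > 0) {
      w <- w * (1 + weight_rel_sd * stats::rnorm(length(w)))
      w <- pmax(w, 0); w <- w / sum(w)
    }
    if (i %in% contamination && length(w) >= 2L) {
      shift <- contamination_strength * w[1L]
      w[1L] <- w[1L] - shift
      w[2L] <- w[2L] + shift
    }
    out[i, ] <- as.numeric(templates %*% w) +
      if (noise_sd > 0) stats::rnorm(n_channels, 0, noise_sd) else 0
  }
  out
}

#' Hotelling T-squared homogeneity monitoring
#'
#' Builds a PCA model of reference spectra and flags samples whose score
#' distance (T-squared: sum of squared scores scaled by the per-component
#' score variances) exceeds the F-distribution control limit at
#' `alpha_level`. When `reference` is omitted the spectra are monitored
#' against themselves (in-model limit); with a separate reference set the
#' new-observation limit is used.
#'
#' @param spectra matrix of spectra to score (rows = samples).
#' @param n_pcs number of principal components (reduced with a warning if
#'   the reference is rank-deficient).
#' @param alpha_level significance level of the control limit
#'   (default 0.01).
#' @param reference optional training spectra matrix.
#' @return data.frame with per-sample `t2`, `limit`, `flag`.
#' @export
hotelling_t2 <- function(spectra, n_pcs = 3L, alpha_level = 0.01, reference = NULL) {
  spectra <- as.matrix(spectra)
  new_obs <- !is.null(reference)
  ref <- if (new_obs) as.matrix(reference) else spectra
  n <- nrow(ref)
  if (n < n_pcs + 2L) stop("need at least n_pcs + 2 reference spectra")
  pc <- stats::prcomp(ref, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  usable <- sum(ev > max(ev) * 1e-10)
  if (usable < n_pcs) {
    warning(sprintf("reference spectra support only %d components; reducing n_pcs from %d",
                    usable, n_pcs))
    n_pcs <- usable
  }
  scores <- scale(spectra, center = pc$center, scale = FALSE) %*%
    pc$rotation[, seq_len(n_pcs), drop = FALSE]
  t2 <- rowSums(sweep(scores^2, 2L, ev[seq_len(n_pcs)], "/"))
  limit <- if (new_obs) {
    n_pcs * (n - 1) * (n + 1) / (n * (n - n_pcs)) *
      stats::qf(1 - alpha_level, n_pcs, n - n_pcs)
  } else {
    n_pcs * (n - 1) / (n - n_pcs) * stats::qf(1 - alpha_level, n_pcs, n - n_pcs)
  }
  data.frame(t2 = t2, limit = limit, flag = t2 > limit)
}

# --- FFC surrogate ----------------------------------------------------------

#' Train the blend-flow (FFC) ensemble regressor
#'
#' Trains an ensemble of feed-forward regressors mapping blend-level
#' features ([ffc_blend_features()]) to log FFC against the virtual
#' plant's ground-truth flow rule, on randomly sampled formulations.
#' Predictions are made member-wise on the FFC scale via
#' [predict_ffc()].
#'
#' @param lib a [material_library()].
#' @param n number of random training formulations (default 500).
#' @param seed integer seed.
#' @param n_members ensemble size (default 20).
#' @param hidden hidden-layer widths (default `c(64, 64)`).
#' @return object of class `ffc_model`.
#' @export
train_ffc_surrogate <- function(lib, n = 500L, seed = 1L, n_members = 20L,
                                hidden = c(64L, 64L)) {
  if (n < 50L) stop("need at least 50 training formulations")
  apis <- names(lib)[vapply(lib, function(r) r$role == "api", logical(1))]
  fbs <- names(lib)[vapply(lib, function(r) r$role == "filler_binder", logical(1))]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  X <- NULL; y <- numeric(0)
  pure_ids <- c(fbs, apis)
  for (i in seq_len(n)) {
    if (i <= length(pure_ids)) {
      # anchor the pure components
      id <- pure_ids[i]
      f <- formulation(id, 1, if (lib_get(lib, id)$role == "api") id else NULL)
    } else {
      placebo <- stats::runif(1) < 0.15
      api <- if (placebo) NULL else sample(apis, 1L)
      loading <- if (placebo) 0 else stats::runif(1, 0, 0.95)
      exc <- sample(fbs, 2L)
      split <- stats::runif(1)
      f <- make_formulation(api, loading, stats::setNames(c(split, 1 - split), exc))
    }
    X <- rbind(X, ffc_blend_features(f, lib))
    y <- c(y, log(ground_truth_ffc(f, lib)))
  }
  ens <- ff_ensemble(X, y, n_members = n_members, hidden = hidden, seed = seed)
  structure(list(ensemble = ens, feature_names = colnames(X), n_train = n,
                 seed = as.integer(seed)),
            class = "ffc_model")
}

#' @export
print.ffc_model <- function(x, ...) {
  cat(sprintf("<ffc_model> ensemble FFC regressor (%d members) on %d blends\n",
              x$ensemble$n_members, x$n_train))
  invisible(x)
}
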