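#' Tablet-models interface
#'
#' A tablet-models object answers one question — given a formulation and a
#' pressure grid, what are the blend FFC and the tablet porosity and
#' tensile strength, with uncertainty? — and is consumed uniformly by the
#' formulation optimiser, the sensitivity sweep, the particle-size study
#' and the closed-loop workflow. Two implementations exist:
#' `ensemble_tablet_models()` wraps the trained process-model ensembles
#' plus the FFC regressor and PCA bases (the digital-formulator stack),
#' and `ground_truth_tablet_models()` exposes the virtual plant's exact
#' laws with zero predictive spread (the test oracle).
#'
#' @param eps_ensemble,sigma_ensemble [train_ensemble()] results for
#'   porosity and log-tensile.
#' @param ffc_model a [train_ffc_surrogate()] result.
#' @param psd_basis,ard_basis the frozen PCA bases the ensembles were
#'   trained with.
#' @return object of class `tablet_models`.
#' @export
ensemble_tablet_models <- function(eps_ensemble, sigma_ensemble, ffc_model,
                                   psd_basis, ard_basis) {
  stopifnot(inherits(eps_ensemble, "tablet_ensemble"),
            inherits(sigma_ensemble, "tablet_ensemble"),
            inherits(ffc_model, "ffc_model"))
  structure(list(type = "ensemble",
                 eps_ensemble = eps_ensemble, sigma_ensemble = sigma_ensemble,
                 ffc_model = ffc_model,
                 psd_basis = psd_basis, ard_basis = ard_basis),
            class = "tablet_models")
}

#' @rdname ensemble_tablet_models
#' @export
ground_truth_tablet_models <- function() {
  structure(list(type = "ground_truth"), class = "tablet_models")
}

#' Fixed-output tablet models
#'
#' A stub implementation returning preset predictions regardless of the
#' formulation — useful for what-if analyses and for exercising the
#' optimiser's constraint arithmetic in isolation.
#'
#' @param ffc,ffc_std preset flow prediction.
#' @param eps_mean,eps_std preset porosity prediction.
#' @param sigma_mean,sigma_std preset tensile prediction (MPa).
#' @return a `tablet_models` object of type `"fixed"`.
#' @export
fixed_tablet_models <- function(ffc, eps_mean, sigma_mean,
                                ffc_std = 0, eps_std = 0, sigma_std = 0) {
  structure(list(type = "fixed", ffc = ffc, ffc_std = ffc_std,
                 eps_mean = eps_mean, eps_std = eps_std,
                 sigma_mean = sigma_mean, sigma_std = sigma_std),
            class = "tablet_models")
}

#' @export
print.tablet_models <- function(x, ...) {
  cat(sprintf("<tablet_models> type: %s\n", x$type))
  invisible(x)
}

#' Predict tablet attributes for a formulation
#'
#' @param models a `tablet_models` object.
#' @param f a [formulation()].
#' @param lib a [material_library()].
#' @param P vector of main compression pressures, MPa.
#' @return list with `ffc`, `ffc_std`, `eps_mean`, `eps_std`,
#'   `sigma_mean`, `sigma_std` (vectors along `P`), member matrices
#'   `eps_members`/`sigma_members` (ensemble models only) and an
#'   `extrapolation` flag.
#' @export
predict_tablet <- function(models, f, lib, P) {
  stopifnot(inherits(models, "tablet_models"))
  if (models$type == "fixed") {
    k <- length(P)
    return(list(ffc = models$ffc, ffc_std = models$ffc_std,
                eps_mean = rep(models$eps_mean, k), eps_std = rep(models$eps_std, k),
                sigma_mean = rep(models$sigma_mean, k),
                sigma_std = rep(models$sigma_std, k),
                eps_members = NULL, sigma_members = NULL, extrapolation = FALSE))
  }
  if (models$type == "ground_truth") {
    law <- make_virtual_material(f, lib, seed = 0L)
    eps <- kawakita_porosity(P, law$params)
    sig <- rd_tensile(eps, law$params)
    return(list(ffc = law$ffc_true, ffc_std = 0,
                eps_mean = eps, eps_std = rep(0, length(P)),
                sigma_mean = sig, sigma_std = rep(0, length(P)),
                eps_members = NULL, sigma_members = NULL,
                extrapolation = FALSE))
  }
  blend <- blend_properties(f, lib)
  pf <- predict_ffc(f, lib, models$ffc_model)
  blend$ffc <- pf$ffc
  api <- if (!is.null(f$api_id)) lib_get(lib, f$api_id) else NULL
  x1 <- assemble_features(blend, f, api, P[1L], models$psd_basis, models$ard_basis)
  X <- matrix(rep(x1, each = length(P)), nrow = length(P),
              dimnames = list(NULL, names(x1)))
  X[, "pressure"] <- P
  pe <- predict(models$eps_ensemble, X)
  ps <- predict(models$sigma_ensemble, X)
  list(ffc = pf$ffc, ffc_std = pf$ffc_std,
       eps_mean = pe$mean, eps_std = pe$std,
       sigma_mean = ps$mean, sigma_std = ps$std,
       eps_members = pe$member_values, sigma_members = ps$member_values,
       extrapolation = any(pe$extrapolation))
}

#' Save / load a trained model bundle
#'
#' Serialises an ensemble tablet-models object to a directory of plain
#' JSON files (per-member weights, standardisation parameters, PCA bases
#' and a manifest with seeds), and reads it back.
#'
#' @param models an `ensemble_tablet_models()` object.
#' @param dir bundle directory (created if needed).
#' @return `dir` (save) or a `tablet_models` object (load).
#' @export
save_model_bundle <- function(models, dir) {
  stopifnot(inherits(models, "tablet_models"), models$type == "ensemble")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  j <- function(x, f) writeLines(jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE,
                                                  null = "null"),
                                 file.path(dir, f))
  dump_ens <- function(ens) {
    list(members = lapply(ens$members, function(m)
           list(W = lapply(m$W, unclass), b = m$b)),
         hidden = ens$hidden, x_mean = ens$x_mean, x_sd = ens$x_sd,
         y_mean = ens$y_mean, y_sd = ens$y_sd, seed = ens$seed,
         n_train = ens$n_train, n_members = ens$n_members)
  }
  j(dump_ens(models$eps_ensemble$ensemble), "eps_ensemble.json")
  j(dump_ens(models$sigma_ensemble$ensemble), "sigma_ensemble.json")
  j(dump_ens(models$ffc_model$ensemble), "ffc_ensemble.json")
  j(list(mean = models$psd_basis$mean, components = models$psd_basis$components,
         evr = models$psd_basis$explained_variance_ratio,
         edges = models$psd_basis$edges, n_components = models$psd_basis$n_components),
    "psd_basis.json")
  j(list(mean = models$ard_basis$mean, components = models$ard_basis$components,
         evr = models$ard_basis$explained_variance_ratio,
         edges = models$ard_basis$edges, n_components = models$ard_basis$n_components),
    "ard_basis.json")
  j(list(eps_seed = models$eps_ensemble$seed, sigma_seed = models$sigma_ensemble$seed,
         ffc_seed = models$ffc_model$seed, version = "1"),
    "manifest.json")
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  rd <- function(f) jsonlite::fromJSON(file.path(dir, f), simplifyDataFrame = FALSE)
  as_mat <- function(w) if (is.matrix(w)) w else matrix(unlist(w), nrow = length(w), byrow = TRUE)
  read_ens <- function(obj) {
    members <- lapply(obj$members, function(m) {
      list(W = lapply(m$W, as_mat), b = lapply(m$b, unlist), ok = TRUE)
    })
    structure(list(members = members, n_members = obj$n_members,
                   hidden = unlist(obj$hidden),
                   x_mean = unlist(obj$x_mean), x_sd = unlist(obj$x_sd),
                   y_mean = obj$y_mean, y_sd = obj$y_sd,
                   seed = obj$seed, n_train = obj$n_train),
              class = "ff_ensemble")
  }
  read_basis <- function(obj) {
    comps <- if (is.matrix(obj$components)) obj$components else
      matrix(unlist(obj$components), ncol = obj$n_components, byrow = TRUE)
    structure(list(mean = unlist(obj$mean), components = comps,
                   explained_variance_ratio = unlist(obj$evr),
                   edges = unlist(obj$edges), degenerate = FALSE,
                   n_components = obj$n_components),
              class = "dist_pca")
  }
  man <- rd("manifest.json")
  eps_ens <- structure(list(ensemble = read_ens(rd("eps_ensemble.json")),
                            target = "porosity", feature_names = feature_names_21,
                            seed = man$eps_seed), class = "tablet_ensemble")
  sig_ens <- structure(list(ensemble = read_ens(rd("sigma_ensemble.json")),
                            target = "log_tensile", feature_names = feature_names_21,
                            seed = man$sigma_seed), class = "tablet_ensemble")
  ffc <- structure(list(ensemble = read_ens(rd("ffc_ensemble.json")),
                        feature_names = NULL, n_train = NA_integer_,
                        seed = man$ffc_seed), class = "ffc_model")
  ensemble_tablet_models(eps_ens, sig_ens, ffc,
                         read_basis(rd("psd_basis.json")),
                         read_basis(rd("ard_basis.json")))
}

#' Train the full digital-formulator model stack from a synthetic corpus
#'
#' Convenience constructor: generates a training corpus on the virtual
#' plant, trains the porosity and log-tensile ensembles and the FFC
#' regressor, and returns the assembled [ensemble_tablet_models()].
#'
#' @param lib a [material_library()].
#' @param n_formulations corpus size in formulations (default 70; with the
#'   default 7-pressure grid this yields about 490 tablets).
#' @param pressures pressure grid, MPa.
#' @param seed master seed for corpus and training.
#' @param n_members ensemble size (default 20).
#' @param noise a [plant_noise()].
#' @param ffc_n FFC-regressor training formulations (default 400).
#' @return a `tablet_models` object of type `"ensemble"`.
#' @export
train_formulator_models <- function(lib, n_formulations = 70L,
                                    pressures = seq(100, 400, by = 50),
                                    seed = 1L, n_members = 20L,
                                    noise = plant_noise(), ffc_n = 400L) {
  corpus <- generate_training_corpus(lib, n_formulations, pressures,
                                     seed = seed, noise = noise)
  eps_ens <- train_ensemble(corpus$records, "porosity", n_members = n_members,
                            seed = seed)
  sig_ens <- train_ensemble(corpus$records, "log_tensile", n_members = n_members,
                            seed = seed + 1L)
  ffc <- train_ffc_surrogate(lib, n = ffc_n, seed = seed + 2L, n_members = n_members)
  ensemble_tablet_models(eps_ens, sig_ens, ffc, corpus$psd_basis, corpus$ard_basis)
}
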