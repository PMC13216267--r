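feature_names_21 <- c("true_density", "bulk_density",
                      "psd_pc1", "psd_pc2", "psd_pc3",
                      "ard_pc1", "ard_pc2", "ard_pc3",
                      "tapped_density", "ffc", "pressure", "api_loading",
                      paste0("descr", 1:9))

#' Assemble the 21-feature process-model input vector
#'
#' Fixed feature ordering: blend true density (1), bulk density (1), three
#' PSD principal-component scores, three aspect-ratio PC scores, tapped
#' density (1), FFC (1), main compression pressure in MPa (1), API mass
#' fraction (1) and the nine API particle-informatics descriptors
#' (zero-filled for placebos).
#'
#' @param blend a [blend_properties()] result that includes `ffc`.
#' @param f the [formulation()].
#' @param api the API [material_record()] (with descriptors), or `NULL`
#'   for a placebo.
#' @param P main compression pressure, MPa (> 0).
#' @param psd_basis,ard_basis frozen [fit_distribution_pca()] bases.
#' @return named numeric vector of length 21.
#' @export
assemble_features <- function(blend, f, api, P, psd_basis, ard_basis) {
  stopifnot(P > 0, f$api_loading >= 0, f$api_loading <= 1)
  if (is.null(blend$ffc)) stop("blend properties must include an FFC value")
  if (!is.null(f$api_id)) {
    if (is.null(api) || is.null(api$descriptors)) {
      stop(sprintf("API '%s' is missing its particle-informatics descriptors", f$api_id))
    }
    descr <- api$descriptors
  } else {
    descr <- rep(0, 9L)
  }
  x <- c(blend$true_density, blend$bulk_density,
         project_distribution(blend$psd, psd_basis),
         project_distribution(blend$ard, ard_basis),
         blend$tapped_density, blend$ffc, P, f$api_loading, descr)
  stats::setNames(x, feature_names_21)
}

corpus_matrix <- function(records) {
  X <- t(vapply(records, `[[`, numeric(21L), "features"))
  colnames(X) <- feature_names_21
  list(X = X,
       porosity = vapply(records, `[[`, numeric(1), "porosity"),
       tensile = vapply(records, `[[`, numeric(1), "tensile"),
       api_id = vapply(records, `[[`, character(1), "api_id"))
}

#' Train a process-model ensemble
#'
#' Trains a 20-member deep ensemble (two ReLU hidden layers of 128 units
#' by default, Adam, early stopping on a 10% internal validation split)
#' mapping the 21 blend/process features to tablet porosity or to the
#' natural logarithm of tensile strength — the log transform encodes the
#' exponential porosity-strength relationship.
#'
#' @param records list of `tablet_record`s (at least 50).
#' @param target `"porosity"` or `"log_tensile"`.
#' @param n_members ensemble size (default 20).
#' @param seed master seed (member seeds are derived from it).
#' @param hidden,lr,batch_size,max_epochs,patience training
#'   hyperparameters, passed to [ff_ensemble()].
#' @return object of class `tablet_ensemble`.
#' @export
train_ensemble <- function(records, target = c("porosity", "log_tensile"),
                           n_members = 20L, seed = 1L, hidden = c(128L, 128L),
                           lr = 1e-3, batch_size = 32L, max_epochs = 2000L,
                           patience = 100L) {
  target <- match.arg(target)
  if (length(records) < 50L) stop("need at least 50 tablet records")
  cm <- corpus_matrix(records)
  y <- if (target == "porosity") cm$porosity else log(cm$tensile)
  if (any(!is.finite(y))) stop("targets contain non-finite values")
  ens <- ff_ensemble(cm$X, y, n_members = n_members, hidden = hidden, lr = lr,
                     batch_size = batch_size, max_epochs = max_epochs,
                     patience = patience, seed = seed)
  structure(list(ensemble = ens, target = target, feature_names = feature_names_21,
                 seed = as.integer(seed)),
            class = "tablet_ensemble")
}

#' @export
print.tablet_ensemble <- function(x, ...) {
  cat(sprintf("<tablet_ensemble> target %s; ", x$target))
  print(x$ensemble)
  invisible(x)
}

#' Ensemble prediction for tablet attributes
#'
#' Mean and member standard deviation of the predicted porosity (fraction)
#' or tensile strength (MPa). Tensile-strength members are exponentiated
#' back to MPa *before* averaging, so the reported mean and spread live on
#' the physical scale. Features more than 3 training standard deviations
#' outside the training envelope set the `extrapolation` flag.
#'
#' @param object a [train_ensemble()] result.
#' @param newdata numeric feature matrix (or single length-21 vector).
#' @param ... unused.
#' @return list of class `ensemble_prediction`: `mean`, `std`,
#'   `member_values` (samples x members), `extrapolation`.
#' @export
predict.tablet_ensemble <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  pr <- predict(object$ensemble, newdata)
  M <- if (object$target == "log_tensile") exp(pr$members) else pr$members
  structure(list(mean = rowMeans(M),
                 std = if (ncol(M) > 1L) apply(M, 1L, stats::sd) else rep(0, nrow(M)),
                 member_values = M,
                 extrapolation = pr$extrapolation,
                 target = object$target),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  unit <- if (x$target == "porosity") "" else " MPa"
  cat(sprintf("<ensemble_prediction> %s: %s%s\n", x$target,
              paste(sprintf("%.4g +/- %.3g", x$mean, x$std), collapse = ", "), unit))
  invisible(x)
}

#' Leave-API-out train/test split
#'
#' Holds out every record of the named APIs for testing; placebo records
#' are always kept in training, so generalisation is assessed on unseen
#' drugs only.
#'
#' @param records list of `tablet_record`s.
#' @param held_out_apis character vector of API ids present in the data.
#' @return list with `train` and `test` record lists.
#' @export
leave_api_out_split <- function(records, held_out_apis) {
  apis <- vapply(records, `[[`, character(1), "api_id")
  missing <- setdiff(held_out_apis, apis)
  if (length(missing)) {
    stop(sprintf("held-out API(s) not present in data: %s", paste(missing, collapse = ", ")))
  }
  test_mask <- apis %in% held_out_apis & apis != "placebo"
  if (!any(test_mask) || all(test_mask)) stop("split leaves an empty train or test set")
  list(train = records[!test_mask], test = records[test_mask])
}

model_r2 <- function(ensemble, records) {
  cm <- corpus_matrix(records)
  y <- if (ensemble$target == "porosity") cm$porosity else log(cm$tensile)
  pr <- predict(ensemble$ensemble, cm$X)
  1 - sum((y - pr$mean)^2) / sum((y - mean(y))^2)
}

#' Permutation feature importance
#'
#' Importance of each input feature as the mean degradation of the
#' ensemble's R-squared (on its native target scale) when that feature's
#' column is shuffled, averaged over `n_repeats` shuffles. Deterministic
#' under `seed`.
#'
#' @param ensemble a [train_ensemble()] result.
#' @param records evaluation records (at least 30).
#' @param n_repeats number of shuffles per feature (at least 2).
#' @param seed RNG seed.
#' @return data.frame sorted by decreasing importance with columns
#'   `feature`, `importance`, `importance_sd`.
#' @export
permutation_importance <- function(ensemble, records, n_repeats = 5L, seed = 1L) {
  stopifnot(inherits(ensemble, "tablet_ensemble"))
  if (length(records) < 30L) stop("need at least 30 records")
  if (n_repeats < 2L) stop("n_repeats must be at least 2")
  cm <- corpus_matrix(records)
  y <- if (ensemble$target == "porosity") cm$porosity else log(cm$tensile)
  sst <- sum((y - mean(y))^2)
  r2 <- function(X) {
    pr <- predict(ensemble$ensemble, X)
    1 - sum((y - pr$mean)^2) / sst
  }
  base <- r2(cm$X)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  drops <- matrix(NA_real_, length(feature_names_21), n_repeats)
  for (j in seq_along(feature_names_21)) {
    for (r in seq_len(n_repeats)) {
      Xp <- cm$X
      Xp[, j] <- sample(Xp[, j])
      drops[j, r] <- base - r2(Xp)
    }
  }
  out <- data.frame(feature = feature_names_21,
                    importance = rowMeans(drops),
                    importance_sd = apply(drops, 1L, stats::sd))
  out[order(-out$importance), , drop = FALSE]
}

#' Sensitivity of tablet attributes to one component's fraction
#'
#' Varies the mass fraction of one formulation component over a grid while
#' rescaling the other filler/binders to keep the fractions summing to 1
#' (API, disintegrant and lubricant fractions stay fixed). For each
#' feasible grid point it reports the predicted FFC and the tensile
#' strength at the reference porosity, obtained by sweeping the pressure
#' grid through the models and interpolating with the
#' Ryshkewitch-Duckworth fit.
#'
#' @param models a tablet-models interface (see [ensemble_tablet_models()]
#'   or [ground_truth_tablet_models()]).
#' @param f the base [formulation()].
#' @param lib a [material_library()].
#' @param vary component id whose fraction is varied (a filler/binder in
#'   `f`).
#' @param grid fractions to evaluate.
#' @param pressures pressure sweep, MPa (default 100-400 step 50).
#' @param eps_star reference porosity (default 0.15).
#' @return data.frame with `fraction`, `ts15`, `ts15_std`, `ffc`,
#'   `ffc_std`; infeasible grid points are dropped with a warning.
#' @export
sensitivity_sweep <- function(models, f, lib, vary, grid,
                              pressures = seq(100, 400, by = 50), eps_star = 0.15) {
  if (!vary %in% f$ids) stop(sprintf("component '%s' is not in the formulation", vary))
  roles <- vapply(f$ids, function(id) lib_get(lib, id)$role, character(1))
  co <- setdiff(f$ids[roles == "filler_binder"], vary)
  fixed_ids <- setdiff(f$ids, c(vary, co))
  fixed_w <- f$w[match(fixed_ids, f$ids)]
  co_w <- f$w[match(co, f$ids)]
  avail <- 1 - sum(fixed_w)
  feasible <- grid >= 0 & grid <= avail + 1e-9
  if (!all(feasible)) {
    warning(sprintf("%d infeasible grid point(s) dropped (co-component fraction would be negative)",
                    sum(!feasible)))
    grid <- grid[feasible]
  }
  rows <- lapply(grid, function(wv) {
    rest <- avail - wv
    w_co <- if (length(co)) rest * co_w / sum(co_w) else numeric(0)
    ids <- c(fixed_ids, vary, co)
    w <- c(fixed_w, wv, w_co)
    keep <- w > 1e-12
    fg <- formulation(ids[keep], w[keep],
                      if (!is.null(f$api_id) && f$api_id %in% ids[keep]) f$api_id)
    pt <- predict_tablet(models, fg, lib, pressures)
    ts <- ts15_from_curves(pt, pressures, eps_star)
    data.frame(fraction = wv, ts15 = ts$mean, ts15_std = ts$std,
               ffc = pt$ffc, ffc_std = pt$ffc_std)
  })
  do.call(rbind, rows)
}

# member-wise R-D interpolation of tensile strength at eps_star
ts15_from_curves <- function(pt, pressures, eps_star) {
  if (!is.null(pt$eps_members) && ncol(pt$eps_members) > 1L) {
    vals <- vapply(seq_len(ncol(pt$eps_members)), function(m) {
      tryCatch(tensile_at_porosity(pt$eps_members[, m], pt$sigma_members[, m], eps_star),
               error = function(e) NA_real_)
    }, numeric(1))
    vals <- vals[is.finite(vals)]
    list(mean = mean(vals), std = stats::sd(vals))
  } else {
    list(mean = tensile_at_porosity(pt$eps_mean, pt$sigma_mean, eps_star), std = 0)
  }
}
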