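#' Tablet formulation
#'
#' An ordered set of components with mass fractions summing to 1. A
#' formulation carries at most one API (`api_id = NULL` for a placebo);
#' conventional direct-compression recipes fix the disintegrant at 3.5 wt%
#' and the lubricant at 1 wt% (see [make_formulation()]).
#'
#' @param ids character vector of material ids.
#' @param fractions mass fractions in `[0, 1]` summing to 1 (1e-9 slack).
#' @param api_id id of the API component, or `NULL` for a placebo.
#' @return object of class `formulation` with fields `ids`, `w`, `api_id`,
#'   `api_loading`.
#' @export
formulation <- function(ids, fractions, api_id = NULL) {
  ids <- as.character(ids)
  w <- as.numeric(fractions)
  stopifnot(length(ids) == length(w), length(ids) >= 1L, !anyDuplicated(ids))
  if (any(w < -1e-12) || any(w > 1 + 1e-12)) stop("mass fractions must lie in [0, 1]")
  w <- pmin(pmax(w, 0), 1)
  if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("mass fractions sum to %.10f, not 1", sum(w)))
  }
  if (!is.null(api_id)) {
    if (!api_id %in% ids) stop(sprintf("api_id '%s' is not a component", api_id))
  }
  loading <- if (is.null(api_id)) 0 else w[match(api_id, ids)]
  structure(list(ids = ids, w = w, api_id = api_id, api_loading = loading),
            class = "formulation")
}

#' @export
print.formulation <- function(x, ...) {
  cat(sprintf("<formulation> %s%s\n",
              paste(sprintf("%s %.1f%%", x$ids, 100 * x$w), collapse = " + "),
              if (is.null(x$api_id)) " (placebo)" else sprintf(" [API: %s]", x$api_id)))
  invisible(x)
}

#' Build a standard direct-compression formulation
#'
#' Combines an API at a given drug loading with filler/binder excipients,
#' a disintegrant and a lubricant. Unless overridden, the disintegrant is
#' fixed at 3.5 wt% and the lubricant at 1 wt%; the excipient fractions are
#' rescaled to fill the remaining mass. Zero-fraction components are
#' dropped, so `api_loading = 1` yields a pure-API formulation and
#' `api_loading = 0` a placebo.
#'
#' @param api_id API material id (ignored when `api_loading` is 0).
#' @param api_loading API mass fraction in `[0, 1]`.
#' @param excipients named numeric vector of relative filler/binder
#'   proportions (rescaled to the available mass).
#' @param disintegrant_id,lubricant_id material ids of the fixed components.
#' @param disintegrant_frac,lubricant_frac their mass fractions.
#' @return a [formulation()].
#' @export
make_formulation <- function(api_id, api_loading, excipients,
                             disintegrant_id = "CCS_SYN", lubricant_id = "MGST_SYN",
                             disintegrant_frac = 0.035, lubricant_frac = 0.01) {
  stopifnot(api_loading >= 0, api_loading <= 1)
  if (api_loading >= 1 - 1e-12) {
    return(formulation(api_id, 1, api_id))
  }
  fixed <- disintegrant_frac + lubricant_frac
  avail <- 1 - api_loading - fixed
  if (avail < -1e-9) stop("api loading plus fixed fractions exceed 1")
  avail <- max(avail, 0)
  exc <- excipients[excipients > 0]
  if (length(exc) == 0L && avail > 1e-9) stop("no excipient available to fill the formulation")
  w_exc <- if (avail > 0) avail * exc / sum(exc) else numeric(0)
  ids <- c(if (api_loading > 0) api_id, names(w_exc), disintegrant_id, lubricant_id)
  w <- c(if (api_loading > 0) api_loading, as.numeric(w_exc),
         disintegrant_frac, lubricant_frac)
  keep <- w > 0
  formulation(ids[keep], w[keep], if (api_loading > 0) api_id else NULL)
}

check_components <- function(f, lib) {
  missing <- setdiff(f$ids, names(lib))
  if (length(missing)) {
    stop(sprintf("component(s) not in library: %s", paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Blend true density
#'
#' Volume-additive (inverse mass-weighted harmonic mean) mixing rule:
#' `rho = 1 / sum(w_i / rho_i)`.
#'
#' @param f a [formulation()].
#' @param lib a [material_library()].
#' @return blend true density, g/cm3.
#' @export
mix_true_density <- function(f, lib) {
  check_components(f, lib)
  rho <- vapply(f$ids, function(id) lib_get(lib, id)$true_density, numeric(1))
  1 / sum(f$w / rho)
}

#' Blend bulk and tapped densities
#'
#' The same volume-additive rule as [mix_true_density()], applied
#' independently to the bulk and tapped specific volumes. The component
#' invariant `bulk <= tapped` carries over to the blend.
#'
#' @inheritParams mix_true_density
#' @return named numeric `c(bulk = , tapped = )`, g/cm3.
#' @export
mix_bulk_tapped <- function(f, lib) {
  check_components(f, lib)
  bulk <- vapply(f$ids, function(id) lib_get(lib, id)$bulk_density, numeric(1))
  tapped <- vapply(f$ids, function(id) lib_get(lib, id)$tapped_density, numeric(1))
  c(bulk = 1 / sum(f$w / bulk), tapped = 1 / sum(f$w / tapped))
}

#' Blend particle-size or aspect-ratio distribution
#'
#' Mass-fraction-weighted bin-wise mixture of the component distributions,
#' renormalised. All components must share the blend grid.
#'
#' @inheritParams mix_true_density
#' @param which `"psd"` or `"ard"`.
#' @return a [binned_dist()].
#' @export
mix_distribution <- function(f, lib, which = c("psd", "ard")) {
  which <- match.arg(which)
  check_components(f, lib)
  ref <- lib_get(lib, f$ids[1L])[[which]]
  dens <- rep(0, length(ref$density))
  for (i in seq_along(f$ids)) {
    d <- lib_get(lib, f$ids[i])[[which]]
    if (!grids_match(d$edges, ref$edges)) {
      stop(sprintf("component '%s' %s grid does not match blend grid", f$ids[i], which))
    }
    dens <- dens + f$w[i] * d$density
  }
  binned_dist(size_grid(ref$edges), dens, tol = Inf)
}

#' Blend-level features for flow prediction
#'
#' Feature vector consumed by the FFC regressor: mixed densities, the Carr
#' compressibility index, log quantiles and span of the blend PSD, fine
#' fractions below 10 and 30 um, and the mean blend aspect ratio.
#'
#' @inheritParams mix_true_density
#' @return named numeric vector of length 11.
#' @export
ffc_blend_features <- function(f, lib) {
  bt <- mix_bulk_tapped(f, lib)
  psd <- mix_distribution(f, lib, "psd")
  ard <- mix_distribution(f, lib, "ard")
  q <- summarize_psd(psd, warn = FALSE)
  ar_mid <- (ard$edges[-1] + ard$edges[-length(ard$edges)]) / 2
  c(true_density = mix_true_density(f, lib),
    bulk_density = unname(bt["bulk"]),
    tapped_density = unname(bt["tapped"]),
    carr = 1 - unname(bt["bulk"]) / unname(bt["tapped"]),
    log_d10 = log(q$d10), log_d50 = log(q$d50), log_d90 = log(q$d90),
    span = q$span,
    fines10 = mass_below(psd, 10), fines30 = mass_below(psd, 30),
    ar_mean = sum(bin_masses(ard) * ar_mid))
}

# mass fraction of a distribution below a size threshold (um)
mass_below <- function(d, x) {
  masses <- bin_masses(d)
  cdf <- stats::approx(d$edges, c(0, cumsum(masses)), xout = x, rule = 2, ties = "ordered")$y
  as.numeric(cdf)
}

#' Predict blend flow function coefficient
#'
#' Applies a trained ensemble FFC regressor (see
#' [train_ffc_surrogate()]) to the blend-level features of a formulation.
#' The prediction is reported at 1.6 kPa consolidation, matching the
#' measurement condition recorded in the library; the consolidation
#' pressure is metadata, not a model input.
#'
#' @inheritParams mix_true_density
#' @param model an FFC regressor of class `ffc_model`.
#' @return list with `ffc`, `ffc_std` and `consolidation_kPa`.
#' @export
predict_ffc <- function(f, lib, model) {
  if (!inherits(model, "ffc_model")) {
    stop("model must be a trained 'ffc_model'; see train_ffc_surrogate()")
  }
  x <- ffc_blend_features(f, lib)
  pr <- predict(model$ensemble, matrix(x, nrow = 1L))
  members <- exp(pr$members[1L, ])
  list(ffc = mean(members),
       ffc_std = if (length(members) > 1L) stats::sd(members) else 0,
       consolidation_kPa = 1.6)
}

#' Jenike flow regime classification
#'
#' Standard FFC classes: very cohesive (FFC < 2), cohesive (2-4),
#' easy-flowing (4-10), free-flowing (>= 10). Boundaries belong to the
#' better-flowing class (strict `FFC < 2` for very cohesive).
#'
#' @param ffc positive flow function coefficient.
#' @return one of `"very_cohesive"`, `"cohesive"`, `"easy_flowing"`,
#'   `"free_flowing"`.
#' @export
classify_flow_regime <- function(ffc) {
  if (!is.finite(ffc) || ffc <= 0) stop("FFC must be positive")
  if (ffc < 2) "very_cohesive"
  else if (ffc < 4) "cohesive"
  else if (ffc < 10) "easy_flowing"
  else "free_flowing"
}

#' Full blend property report
#'
#' @inheritParams predict_ffc
#' @param ffc_model optional trained `ffc_model`; without it the FFC fields
#'   are omitted.
#' @return list of class `blend_properties`: densities, mixed `psd` and
#'   `ard`, and (when a model is given) `ffc`, `ffc_std`, `flow_regime`.
#' @export
blend_properties <- function(f, lib, ffc_model = NULL) {
  bt <- mix_bulk_tapped(f, lib)
  out <- list(true_density = mix_true_density(f, lib),
              bulk_density = unname(bt["bulk"]),
              tapped_density = unname(bt["tapped"]),
              psd = mix_distribution(f, lib, "psd"),
              ard = mix_distribution(f, lib, "ard"))
  if (!is.null(ffc_model)) {
    pf <- predict_ffc(f, lib, ffc_model)
    out$ffc <- pf$ffc
    out$ffc_std <- pf$ffc_std
    out$flow_regime <- classify_flow_regime(pf$ffc)
  }
  structure(out, class = "blend_properties")
}

#' @export
print.blend_properties <- function(x, ...) {
  cat(sprintf("<blend_properties> rho(true/bulk/tapped) = %.3f/%.3f/%.3f g/cm3%s\n",
              x$true_density, x$bulk_density, x$tapped_density,
              if (is.null(x$ffc)) "" else
                sprintf("; FFC %.2f +/- %.2f (%s)", x$ffc, x$ffc_std, x$flow_regime)))
  invisible(x)
}

#' Export a blend report as JSON
#'
#' @param f a [formulation()].
#' @param props a [blend_properties()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blend_report <- function(f, props, path) {
  q <- summarize_psd(props$psd, warn = FALSE)
  rep <- list(formulation = list(ids = f$ids, fractions = f$w, api_id = f$api_id),
              true_density = props$true_density,
              bulk_density = props$bulk_density,
              tapped_density = props$tapped_density,
              psd_summary = q,
              ffc = props$ffc, ffc_std = props$ffc_std,
              flow_regime = props$flow_regime)
  writeLines(jsonlite::toJSON(rep, digits = NA, auto_unbox = TRUE, null = "null"), path)
  invisible(path)
}
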