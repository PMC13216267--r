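#' Default synthetic API particle-size specifications
#'
#' Sixteen illustrative log-normal PSD specifications — eight unimodal
#' (UMD1-UMD8) and eight bimodal (BMD1-BMD8) — spanning median sizes of
#' 10-150 um with generally increasing median and/or span along each
#' series (UMD1/UMD2 share a 10 um median with different spreads; UMD7 is
#' deliberately narrow, giving few fines despite a smaller median than
#' UMD8). User-overridable.
#'
#' @return named list of [psd_spec()]s.
#' @export
default_psd_specs <- function() {
  u_d50 <- c(10, 10, 20, 35, 60, 90, 120, 150)
  u_sg <- c(1.4, 1.8, 1.6, 1.8, 1.8, 1.9, 1.3, 2.2)
  specs <- list()
  for (i in 1:8) {
    specs[[sprintf("UMD%d", i)]] <- psd_spec("unimodal", u_d50[i], u_sg[i])
  }
  b_fine <- c(8, 8, 15, 25, 40, 60, 60, 90)
  b_coarse <- c(40, 60, 80, 120, 160, 200, 250, 300)
  b_wf <- c(0.7, 0.6, 0.55, 0.5, 0.45, 0.4, 0.25, 0.2)
  b_sg <- c(1.5, 1.6, 1.5, 1.6, 1.7, 1.7, 1.4, 1.6)
  for (i in 1:8) {
    specs[[sprintf("BMD%d", i)]] <- psd_spec("bimodal",
                                             d50 = c(b_fine[i], b_coarse[i]),
                                             spread = c(b_sg[i], b_sg[i]),
                                             weights = c(b_wf[i], 1 - b_wf[i]))
  }
  specs
}

#' Particle-size sweep configuration
#'
#' The study design: each synthetic API PSD is imposed on a template API
#' record (all other API properties held fixed), formulated with a fixed
#' 1:1 lactose/MCC filler pair, 3.5% disintegrant and 1% lubricant, at
#' drug loadings from 0 (placebo) to 100% (pure API) in 20% steps; tablet
#' attributes are predicted over 100-400 MPa in 50 MPa steps and the
#' tensile strength is interpolated at 15% porosity.
#'
#' @param psd_specs named list of [psd_spec()]s (default
#'   [default_psd_specs()]).
#' @param loadings drug-loading grid (default `seq(0, 1, 0.2)`).
#' @param pressures pressure grid, MPa (default `seq(100, 400, 50)`).
#' @param template_api id of the API whose non-PSD properties are reused.
#' @param excipients named relative fractions of the base filler/binders.
#' @param eps_star reference porosity for strength interpolation.
#' @return list of class `sweep_config`.
#' @export
psd_sweep_config <- function(psd_specs = default_psd_specs(),
                             loadings = seq(0, 1, by = 0.2),
                             pressures = seq(100, 400, by = 50),
                             template_api = "API_A",
                             excipients = c(LAC_A = 0.5, MCC_A = 0.5),
                             eps_star = 0.15) {
  stopifnot(all(loadings >= 0), all(loadings <= 1),
            all(pressures > 0), !is.unsorted(pressures))
  structure(list(psd_specs = psd_specs, loadings = loadings,
                 pressures = pressures, template_api = template_api,
                 excipients = excipients, eps_star = eps_star),
            class = "sweep_config")
}

# template API with a synthetic PSD imposed; other properties unchanged
synthetic_api_record <- function(id, spec, template) {
  psd <- lognormal_psd(spec, size_grid(template$psd$edges))
  material_record(id, "api", template$true_density, template$bulk_density,
                  template$tapped_density, psd = psd, ard = template$ard,
                  descriptors = template$descriptors)
}

#' Run the API particle-size manufacturability sweep
#'
#' For every (PSD spec, drug loading) cell: builds the formulation,
#' predicts the blend FFC (at 1.6 kPa) and the porosity/tensile curves
#' over the pressure grid through `models`, and interpolates the tensile
#' strength at the reference porosity with the Ryshkewitch-Duckworth fit.
#' Cells whose fit fails are flagged and the sweep continues. Rows are
#' independent, so the result is invariant to the order of the specs.
#'
#' @param cfg a [psd_sweep_config()].
#' @param models a `tablet_models` interface.
#' @param lib a [material_library()] containing the template API and the
#'   base excipients.
#' @return data.frame of class `psd_sweep` with one row per cell:
#'   `psd_id`, `mode`, `loading`, `ffc`, `ffc_std`, `ts15`, `ts15_std`,
#'   `flagged`.
#' @export
run_psd_sweep <- function(cfg, models, lib) {
  stopifnot(inherits(cfg, "sweep_config"))
  template <- lib_get(lib, cfg$template_api)
  recs <- unclass(lib)
  for (nm in names(cfg$psd_specs)) {
    recs[[nm]] <- synthetic_api_record(nm, cfg$psd_specs[[nm]], template)
  }
  lib2 <- material_library(recs)
  rows <- list()
  for (nm in names(cfg$psd_specs)) {
    for (loading in cfg$loadings) {
      f <- if (loading == 0) {
        make_formulation(NULL, 0, cfg$excipients)
      } else {
        make_formulation(nm, loading, cfg$excipients)
      }
      row <- tryCatch({
        pt <- predict_tablet(models, f, lib2, cfg$pressures)
        ts <- ts15_from_curves(pt, cfg$pressures, cfg$eps_star)
        data.frame(psd_id = nm, mode = cfg$psd_specs[[nm]]$mode, loading = loading,
                   ffc = pt$ffc, ffc_std = pt$ffc_std,
                   ts15 = ts$mean, ts15_std = ts$std, flagged = FALSE)
      }, error = function(e) {
        data.frame(psd_id = nm, mode = cfg$psd_specs[[nm]]$mode, loading = loading,
                   ffc = NA_real_, ffc_std = NA_real_,
                   ts15 = NA_real_, ts15_std = NA_real_, flagged = TRUE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("psd_sweep", class(out))
  out
}

#' Qualitative trend report of a particle-size sweep
#'
#' Per-PSD monotonicity statistics (sign of the Spearman correlation of
#' tensile strength at the reference porosity, and of FFC, with drug
#' loading) plus heat-map-ready matrices (PSD x loading). Flagged cells
#' are excluded and counted.
#'
#' @param results a [run_psd_sweep()] data.frame.
#' @return list of class `psd_trend`: `trends` (per-PSD data.frame),
#'   `ts15_matrix`, `ffc_matrix`, `n_flagged`.
#' @export
trend_report <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("psd_id", "loading", "ffc", "ts15") %in% names(results)))
  ok <- !results$flagged
  ids <- unique(results$psd_id)
  loadings <- sort(unique(results$loading))
  sgn <- function(v, l) {
    if (length(unique(v[is.finite(v)])) < 2L) return(0)
    sign(stats::cor(l, v, method = "spearman"))
  }
  trends <- do.call(rbind, lapply(ids, function(id) {
    sub <- results[ok & results$psd_id == id, ]
    data.frame(psd_id = id,
               ts15_trend = sgn(sub$ts15, sub$loading),
               ffc_trend = sgn(sub$ffc, sub$loading))
  }))
  mat <- function(col) {
    m <- matrix(NA_real_, length(ids), length(loadings),
                dimnames = list(ids, paste0(100 * loadings, "%")))
    for (i in seq_len(nrow(results))) {
      if (ok[i]) m[results$psd_id[i], paste0(100 * results$loading[i], "%")] <- results[[col]][i]
    }
    m
  }
  structure(list(trends = trends, ts15_matrix = mat("ts15"), ffc_matrix = mat("ffc"),
                 n_flagged = sum(results$flagged)),
            class = "psd_trend")
}

#' @export
print.psd_trend <- function(x, ...) {
  cat(sprintf("<psd_trend> %d PSDs x %d loadings; %d flagged cells\n",
              nrow(x$ts15_matrix), ncol(x$ts15_matrix), x$n_flagged))
  cat(sprintf("  TS@ref decreasing with loading: %d/%d PSDs; FFC decreasing: %d/%d\n",
              sum(x$trends$ts15_trend < 0), nrow(x$trends),
              sum(x$trends$ffc_trend < 0), nrow(x$trends)))
  invisible(x)
}

#' Export sweep results as CSV
#'
#' @param results a [run_psd_sweep()] data.frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
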