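#' Particle-size bin grid
#'
#' A size grid is the shared set of bin edges on which all particle-size
#' distributions (PSDs) in a material library live. Edges are in micrometres
#' and must be strictly increasing; the default library grid is log-spaced.
#'
#' @param edges numeric vector of strictly increasing bin edges (um). At
#'   least two edges; all non-negative, and at most the first may be zero
#'   (used by the dimensionless aspect-ratio grid on (0, 1]).
#' @return an object of class `size_grid` (numeric edges with attributes).
#' @seealso [default_size_grid()], [default_aspect_grid()]
#' @export
size_grid <- function(edges) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L) {
    stop("a size grid needs at least 2 edges")
  }
  if (any(!is.finite(edges)) || any(edges < 0) || any(edges[-1] <= 0)) {
    stop("size grid edges must be finite and positive (first edge may be 0)")
  }
  if (any(diff(edges) <= 0)) {
    stop("size grid edges must be strictly increasing")
  }
  structure(edges, class = "size_grid")
}

#' Default particle-size grid
#'
#' 96 log-spaced bins spanning 0.05-20000 um. The wide tails keep the
#' log-normal generator's span requirement (`[d50/50, d50*50]` inside the
#' grid) satisfiable for both micronised APIs and coarse bimodal
#' excipient distributions, at a bin resolution of about 0.06 decades.
#'
#' @param n_bins number of bins (default 96).
#' @param lower,upper grid limits in um.
#' @return a [size_grid()].
#' @export
default_size_grid <- function(n_bins = 96L, lower = 0.05, upper = 20000) {
  size_grid(exp(seq(log(lower), log(upper), length.out = n_bins + 1L)))
}

#' Default aspect-ratio grid
#'
#' 32 linear bins on (0, 1] for dimensionless particle aspect ratio.
#'
#' @param n_bins number of bins (default 32).
#' @return a [size_grid()].
#' @export
default_aspect_grid <- function(n_bins = 32L) {
  size_grid(seq(0, 1, length.out = n_bins + 1L))
}

grids_match <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(as.numeric(a) - as.numeric(b)) <= tol * pmax(1, abs(as.numeric(a))))
}

#' Binned distribution on a size grid
#'
#' Volume(mass)-weighted density per bin; the integral over all bins
#' (density times bin width) must be 1.
#'
#' @param grid a [size_grid()].
#' @param density non-negative density values, one per bin
#'   (`length(grid) - 1`).
#' @param renormalise if the integral is off from 1 by at most `tol`,
#'   rescale silently; beyond that, error.
#' @param tol allowed normalisation slack before rejection (default 1e-6).
#' @return object of class `binned_dist` with fields `edges`, `density`.
#' @export
binned_dist <- function(grid, density, renormalise = TRUE, tol = 1e-6) {
  edges <- as.numeric(size_grid(grid))
  density <- as.numeric(density)
  if (length(density) != length(edges) - 1L) {
    stop("density must have one value per bin")
  }
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("densities must be finite and non-negative")
  }
  total <- sum(density * diff(edges))
  if (total <= 0) stop("distribution has zero total mass")
  if (abs(total - 1) > tol) {
    if (!renormalise) stop(sprintf("distribution integral %.8f is not 1", total))
    stop(sprintf("distribution integral %.8f deviates from 1 by more than %g", total, tol))
  }
  # renormalise only when measurably off; an integral within 1e-12 of 1 is
  # left untouched so that serialisation round-trips are bit-faithful
  if (abs(total - 1) > 1e-12) density <- density / total
  structure(list(edges = edges, density = density), class = "binned_dist")
}

#' @export
print.binned_dist <- function(x, ...) {
  q <- summarize_psd(x, warn = FALSE)
  cat(sprintf("<binned_dist> %d bins on [%g, %g]; d10/d50/d90 = %.3g/%.3g/%.3g, span %.3g\n",
              length(x$density), min(x$edges), max(x$edges), q$d10, q$d50, q$d90, q$span))
  invisible(x)
}

bin_masses <- function(d) d$density * diff(d$edges)

dist_from_masses <- function(edges, masses) {
  binned_dist(size_grid(edges), masses / diff(edges), tol = Inf)
}

#' Parametric specification of a log-normal PSD
#'
#' Unimodal PSDs are a single log-normal (median `d50`, geometric spread
#' `sigma_g`); bimodal PSDs are a two-component weighted mixture.
#'
#' @param mode `"unimodal"` or `"bimodal"`.
#' @param d50 numeric median(s) in um (length 1 or 2).
#' @param spread geometric standard deviation(s), > 1 for a non-degenerate
#'   distribution (same length as `d50`).
#' @param weights mixture weights in (0,1) summing to 1 (bimodal only).
#' @return an object of class `psd_spec`.
#' @export
psd_spec <- function(mode = c("unimodal", "bimodal"), d50, spread, weights = NULL) {
  mode <- match.arg(mode)
  k <- if (mode == "unimodal") 1L else 2L
  d50 <- as.numeric(d50); spread <- as.numeric(spread)
  if (length(d50) != k || length(spread) != k) {
    stop(sprintf("%s spec needs %d d50/spread value(s)", mode, k))
  }
  if (any(d50 <= 0) || any(spread <= 0)) stop("d50 and spread must be positive")
  if (mode == "bimodal") {
    if (is.null(weights) || length(weights) != 2L) stop("bimodal spec needs 2 weights")
    weights <- as.numeric(weights)
    if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
      stop("weights must be non-negative and sum to 1")
    }
  } else {
    weights <- 1
  }
  structure(list(mode = mode, d50 = d50, spread = spread, weights = weights),
            class = "psd_spec")
}

#' Generate a log-normal PSD on a grid
#'
#' Bins a (mixture of) log-normal distribution(s) onto `grid` by exact
#' integration of the log-normal CDF over each bin, then renormalises.
#' Truncation loss beyond the grid of more than 1% is an error, signalling
#' that a wider grid is needed.
#'
#' @param spec a [psd_spec()].
#' @param grid a [size_grid()] spanning at least `[d50/50, d50*50]` for each
#'   component.
#' @return a [binned_dist()].
#' @export
lognormal_psd <- function(spec, grid) {
  stopifnot(inherits(spec, "psd_spec"))
  edges <- as.numeric(size_grid(grid))
  lo <- min(edges[edges > 0]); hi <- max(edges)
  masses <- rep(0, length(edges) - 1L)
  for (i in seq_along(spec$d50)) {
    d50 <- spec$d50[i]
    if (lo > d50 / 50 || hi < d50 * 50) {
      stop(sprintf("grid [%g, %g] does not span [d50/50, d50*50] for d50=%g; widen the grid",
                   lo, hi, d50))
    }
    sdlog <- log(max(spec$spread[i], 1 + 1e-12))
    cdf <- stats::plnorm(edges, meanlog = log(d50), sdlog = sdlog)
    m <- diff(cdf)
    loss <- 1 - sum(m)
    if (loss > 0.01) {
      stop(sprintf("truncation mass loss %.3f%% exceeds 1%%; widen the grid", 100 * loss))
    }
    masses <- masses + spec$weights[i] * m
  }
  dist_from_masses(edges, masses / sum(masses))
}

#' Quantile summary of a binned distribution
#'
#' Computes d10, d50, d90 by interpolating the cumulative mass on the bin
#' edges (geometrically within bins for positive grids) and the span
#' `(d90 - d10) / d50`, the standard laser-diffraction width measure.
#'
#' @param d a [binned_dist()].
#' @param warn warn on degenerate single-bin distributions.
#' @return list with `d10`, `d50`, `d90`, `span`.
#' @export
summarize_psd <- function(d, warn = TRUE) {
  stopifnot(inherits(d, "binned_dist"))
  masses <- bin_masses(d)
  occupied <- which(masses > 1e-12)
  if (length(occupied) == 1L) {
    if (warn) warning("distribution is concentrated in a single bin; span is 0")
    e <- d$edges[c(occupied, occupied + 1L)]
    mid <- if (e[1] > 0) sqrt(e[1] * e[2]) else mean(e)
    return(list(d10 = mid, d50 = mid, d90 = mid, span = 0))
  }
  cdf <- c(0, cumsum(masses))
  # interpolate in log size when the grid is positive (log-spaced convention)
  xs <- if (d$edges[1] > 0) log(d$edges) else d$edges
  qfun <- function(p) {
    x <- stats::approx(cdf, xs, xout = p, ties = "ordered")$y
    if (d$edges[1] > 0) exp(x) else x
  }
  q <- vapply(c(0.1, 0.5, 0.9), qfun, numeric(1))
  list(d10 = q[1], d50 = q[2], d90 = q[3], span = (q[3] - q[1]) / q[2])
}

#' Raw-material record
#'
#' One raw material's measured physical properties and its formulation role.
#' Densities are in g/cm3 and must satisfy
#' `0 < bulk <= tapped <= true`; the optional flow function coefficient
#' (FFC, at 1.6 kPa consolidation) must be positive; the nine
#' particle-informatics descriptors are required for APIs and absent
#' otherwise.
#'
#' @param id material identifier.
#' @param role one of `"api"`, `"filler_binder"`, `"disintegrant"`,
#'   `"lubricant"`.
#' @param true_density,bulk_density,tapped_density densities, g/cm3.
#' @param psd,ard particle-size and aspect-ratio [binned_dist()]s.
#' @param ffc_measured optional measured FFC at 1.6 kPa.
#' @param descriptors numeric length-9 particle-informatics descriptor
#'   vector (APIs only).
#' @return object of class `material_record`.
#' @export
material_record <- function(id, role, true_density, bulk_density, tapped_density,
                            psd, ard, ffc_measured = NULL, descriptors = NULL) {
  role <- match.arg(role, c("api", "filler_binder", "disintegrant", "lubricant"))
  for (nm in c("true_density", "bulk_density", "tapped_density")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("material '%s': %s must be a positive scalar", id, nm))
    }
  }
  if (!(bulk_density <= tapped_density && tapped_density <= true_density)) {
    stop(sprintf("material '%s': densities must satisfy bulk <= tapped <= true (got %.4g/%.4g/%.4g)",
                 id, bulk_density, tapped_density, true_density))
  }
  stopifnot(inherits(psd, "binned_dist"), inherits(ard, "binned_dist"))
  if (!is.null(ffc_measured)) {
    if (!is.finite(ffc_measured) || ffc_measured <= 0) {
      stop(sprintf("material '%s': ffc_measured must be positive", id))
    }
  }
  if (role == "api") {
    if (is.null(descriptors) || length(descriptors) != 9L || any(!is.finite(descriptors))) {
      stop(sprintf("API '%s' requires exactly 9 finite particle-informatics descriptors", id))
    }
    descriptors <- as.numeric(descriptors)
  } else if (!is.null(descriptors)) {
    stop(sprintf("material '%s' (role %s) must not carry API descriptors", id, role))
  }
  structure(list(id = as.character(id), role = role,
                 true_density = true_density, bulk_density = bulk_density,
                 tapped_density = tapped_density, psd = psd, ard = ard,
                 ffc_measured = ffc_measured, descriptors = descriptors),
            class = "material_record")
}

#' @export
print.material_record <- function(x, ...) {
  cat(sprintf("<material_record> %s [%s] rho(true/bulk/tapped) = %.3g/%.3g/%.3g g/cm3%s\n",
              x$id, x$role, x$true_density, x$bulk_density, x$tapped_density,
              if (is.null(x$ffc_measured)) "" else sprintf(", FFC %.2f", x$ffc_measured)))
  invisible(x)
}

#' Assemble a material library
#'
#' @param records list of [material_record()]s with unique ids.
#' @return named list of records, class `material_library`.
#' @export
material_library <- function(records) {
  stopifnot(all(vapply(records, inherits, logical(1), "material_record")))
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate material ids in library")
  structure(stats::setNames(records, ids), class = "material_library")
}

#' @export
print.material_library <- function(x, ...) {
  roles <- vapply(x, `[[`, character(1), "role")
  cat(sprintf("<material_library> %d materials (%s)\n", length(x),
              paste(sprintf("%d %s", table(roles), names(table(roles))), collapse = ", ")))
  invisible(x)
}

lib_get <- function(lib, id) {
  rec <- lib[[id]]
  if (is.null(rec)) stop(sprintf("material '%s' not found in library", id))
  rec
}

record_to_row <- function(rec) {
  j <- function(x) as.character(jsonlite::toJSON(x, digits = I(17)))
  # scalars go through %.17g so the CSV round-trips bit-faithfully
  s <- function(x) sprintf("%.17g", x)
  data.frame(
    id = rec$id, role = rec$role,
    true_density = s(rec$true_density), bulk_density = s(rec$bulk_density),
    tapped_density = s(rec$tapped_density),
    ffc_measured = if (is.null(rec$ffc_measured)) NA_character_ else s(rec$ffc_measured),
    descriptors = if (is.null(rec$descriptors)) "" else j(rec$descriptors),
    psd_edges = j(rec$psd$edges), psd_density = j(rec$psd$density),
    ard_edges = j(rec$ard$edges), ard_density = j(rec$ard$density),
    stringsAsFactors = FALSE)
}

row_to_record <- function(row) {
  need <- c("id", "role", "true_density", "bulk_density", "tapped_density",
            "psd_edges", "psd_density", "ard_edges", "ard_density")
  absent <- function(f) {
    !f %in% names(row) || is.na(row[[f]]) || identical(row[[f]], "")
  }
  missing <- need[vapply(need, absent, logical(1))]
  if (length(missing)) {
    stop(sprintf("record '%s': missing field(s) %s",
                 if (!is.null(row$id) && !is.na(row$id)) row$id else "?",
                 paste(missing, collapse = ", ")))
  }
  p <- function(s) as.numeric(jsonlite::fromJSON(s))
  material_record(
    id = row$id, role = row$role,
    true_density = row$true_density, bulk_density = row$bulk_density,
    tapped_density = row$tapped_density,
    psd = binned_dist(size_grid(p(row$psd_edges)), p(row$psd_density)),
    ard = binned_dist(size_grid(p(row$ard_edges)), p(row$ard_density)),
    ffc_measured = if (is.na(row$ffc_measured)) NULL else row$ffc_measured,
    descriptors = if (identical(row$descriptors, "") || is.na(row$descriptors)) NULL
                  else p(row$descriptors))
}

#' Read / write a material library
#'
#' Two equivalent lossless on-disk formats: CSV (one row per material,
#' distribution columns serialised as JSON arrays) and JSON (one object per
#' material). The format is chosen from the file extension.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return `load_material_library` returns a [material_library()];
#'   `save_material_library` returns `path` invisibly.
#' @export
load_material_library <- function(path) {
  if (!file.exists(path)) stop(sprintf("library file '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(descriptors = "character"))
    recs <- lapply(seq_len(nrow(df)), function(i) row_to_record(df[i, , drop = FALSE]))
  } else if (ext == "json") {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    recs <- lapply(raw, function(r) {
      need <- c("id", "role", "true_density", "bulk_density", "tapped_density",
                "psd_edges", "psd_density", "ard_edges", "ard_density")
      missing <- setdiff(need, names(r))
      if (length(missing)) {
        stop(sprintf("record '%s': missing field(s) %s",
                     if (!is.null(r$id)) r$id else "?", paste(missing, collapse = ", ")))
      }
      material_record(
        id = r$id, role = r$role, true_density = r$true_density,
        bulk_density = r$bulk_density, tapped_density = r$tapped_density,
        psd = binned_dist(size_grid(unlist(r$psd_edges)), unlist(r$psd_density)),
        ard = binned_dist(size_grid(unlist(r$ard_edges)), unlist(r$ard_density)),
        ffc_measured = r$ffc_measured, descriptors = unlist(r$descriptors))
    })
  } else {
    stop("unsupported library format: use .csv or .json")
  }
  material_library(recs)
}

#' @param lib a [material_library()].
#' @rdname load_material_library
#' @export
save_material_library <- function(lib, path) {
  stopifnot(inherits(lib, "material_library"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- do.call(rbind, lapply(lib, record_to_row))
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext == "json") {
    objs <- lapply(lib, function(rec) {
      list(id = rec$id, role = rec$role, true_density = rec$true_density,
           bulk_density = rec$bulk_density, tapped_density = rec$tapped_density,
           ffc_measured = rec$ffc_measured, descriptors = rec$descriptors,
           psd_edges = rec$psd$edges, psd_density = rec$psd$density,
           ard_edges = rec$ard$edges, ard_density = rec$ard$density)
    })
    writeLines(jsonlite::toJSON(unname(objs), digits = I(17), auto_unbox = TRUE,
                                null = "null"),
               path)
  } else {
    stop("unsupported library format: use .csv or .json")
  }
  invisible(path)
}

#' Principal-component basis for binned distributions
#'
#' Fits a PCA basis (mean vector plus ordered orthonormal components) to a
#' set of distributions on a common grid. The basis is fit once on training
#' blend distributions and frozen; later candidates are projected onto it
#' with [project_distribution()].
#'
#' @param dists list of [binned_dist()]s on a common grid (at least
#'   `n_components + 1`).
#' @param n_components number of components to retain (default 3).
#' @return object of class `dist_pca` with fields `mean`, `components`
#'   (bins x k, orthonormal columns), `explained_variance_ratio`, `edges`,
#'   `degenerate`.
#' @export
fit_distribution_pca <- function(dists, n_components = 3L) {
  stopifnot(length(dists) >= n_components + 1L,
            all(vapply(dists, inherits, logical(1), "binned_dist")))
  edges <- dists[[1L]]$edges
  for (d in dists) {
    if (!grids_match(edges, d$edges)) stop("distributions are not on a common grid")
  }
  X <- do.call(rbind, lapply(dists, `[[`, "density"))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  tot_var <- sum(Xc^2) / (nrow(X) - 1L)
  degenerate <- tot_var < 1e-20
  if (degenerate) {
    warning("all distributions identical: PCA basis is degenerate, scores will be 0")
    comps <- matrix(0, ncol(X), n_components)
    comps[cbind(seq_len(min(n_components, ncol(X))), seq_len(min(n_components, ncol(X))))] <- 1
    evr <- rep(NA_real_, n_components)
  } else {
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(pc$rotation))
    comps <- pc$rotation[, seq_len(k), drop = FALSE]
    if (k < n_components) {
      pad <- matrix(0, ncol(X), n_components - k)
      comps <- cbind(comps, pad)
    }
    evr <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  }
  structure(list(mean = mu, components = comps,
                 explained_variance_ratio = evr,
                 edges = edges, degenerate = degenerate,
                 n_components = as.integer(n_components)),
            class = "dist_pca")
}

#' Project a distribution onto a PCA basis
#'
#' @param d a [binned_dist()] on the basis grid.
#' @param basis a [fit_distribution_pca()] result.
#' @return numeric score vector of length `basis$n_components`.
#' @export
project_distribution <- function(d, basis) {
  stopifnot(inherits(d, "binned_dist"), inherits(basis, "dist_pca"))
  if (!grids_match(d$edges, basis$edges)) stop("distribution grid does not match PCA basis grid")
  as.numeric(crossprod(basis$components, d$density - basis$mean))
}

#' Reconstruct a distribution from PCA scores (diagnostic)
#'
#' @param scores numeric scores as returned by [project_distribution()].
#' @inheritParams project_distribution
#' @return numeric density vector (not renormalised).
#' @export
reconstruct_distribution <- function(scores, basis) {
  stopifnot(inherits(basis, "dist_pca"))
  as.numeric(basis$mean + basis$components %*% scores)
}
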