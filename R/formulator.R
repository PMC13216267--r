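#' Robust-constraint configuration
#'
#' Thresholds and risk factors of the robust formulation optimisation:
#' the candidate must promise a tensile strength above `theta_sigma`
#' (2 MPa default) and a porosity above `theta_eps` (0.15 default) at the
#' initial pressure, each discounted by `alpha` (or `beta`) times the
#' ensemble's predictive standard deviation. Larger risk factors make the
#' optimisation more conservative.
#'
#' @param theta_sigma tensile-strength floor, MPa (default 2).
#' @param theta_eps porosity floor, fraction (default 0.15).
#' @param alpha,beta risk factors on the tensile / porosity uncertainty
#'   (default 0.2 each).
#' @return list of class `constraint_config`.
#' @export
constraint_config <- function(theta_sigma = 2, theta_eps = 0.15,
                              alpha = 0.2, beta = 0.2) {
  stopifnot(theta_sigma > 0, theta_eps > 0, alpha >= 0, beta >= 0)
  structure(list(theta_sigma = theta_sigma, theta_eps = theta_eps,
                 alpha = alpha, beta = beta), class = "constraint_config")
}

#' Filter the excipient subset for optimisation
#'
#' Restricts the library's filler/binders to an allow-list, removes denied
#' materials, and records incompatible pairs which
#' [optimise_formulation()] then never co-selects.
#'
#' @param lib a [material_library()].
#' @param allow optional character vector of permitted ids.
#' @param deny optional character vector of excluded ids.
#' @param deny_pairs optional list of length-2 character vectors of
#'   incompatible pairs.
#' @return list of class `excipient_subset` with `ids` and `deny_pairs`.
#' @export
excipient_subset_filter <- function(lib, allow = NULL, deny = NULL, deny_pairs = NULL) {
  fbs <- names(lib)[vapply(lib, function(r) r$role == "filler_binder", logical(1))]
  unknown <- setdiff(c(allow, deny, unlist(deny_pairs)), names(lib))
  if (length(unknown)) {
    stop(sprintf("unknown material id(s): %s", paste(unknown, collapse = ", ")))
  }
  ids <- fbs
  if (!is.null(allow)) ids <- intersect(ids, allow)
  ids <- setdiff(ids, deny)
  if (length(ids) == 0L) stop("excipient subset is empty after filtering")
  structure(list(ids = ids, deny_pairs = deny_pairs), class = "excipient_subset")
}

#' Formulation optimisation problem
#'
#' @param api_id API material id.
#' @param api_loading drug loading (mass fraction).
#' @param subset an [excipient_subset_filter()] result (or character
#'   vector of filler/binder ids).
#' @param lib a [material_library()].
#' @param models a `tablet_models` interface.
#' @param constraints a [constraint_config()].
#' @param P_bounds initial-pressure bounds, MPa (default `c(50, 400)`,
#'   inside the model training envelope).
#' @param disintegrant_id,lubricant_id,disintegrant_frac,lubricant_frac
#'   the fixed components (defaults 3.5 wt% / 1 wt%).
#' @return list of class `formulation_problem`.
#' @export
formulation_problem <- function(api_id, api_loading, subset, lib, models,
                                constraints = constraint_config(),
                                P_bounds = c(50, 400),
                                disintegrant_id = "CCS_SYN", lubricant_id = "MGST_SYN",
                                disintegrant_frac = 0.035, lubricant_frac = 0.01) {
  if (is.character(subset)) subset <- excipient_subset_filter(lib, allow = subset)
  stopifnot(inherits(subset, "excipient_subset"), inherits(models, "tablet_models"),
            api_loading >= 0, api_loading < 1)
  avail <- 1 - api_loading - disintegrant_frac - lubricant_frac
  if (avail <= 0) stop("no mass available for filler/binders at this loading")
  structure(list(api_id = api_id, api_loading = api_loading, subset = subset,
                 lib = lib, models = models, constraints = constraints,
                 P_bounds = P_bounds,
                 disintegrant_id = disintegrant_id, lubricant_id = lubricant_id,
                 disintegrant_frac = disintegrant_frac, lubricant_frac = lubricant_frac,
                 avail = avail),
            class = "formulation_problem")
}

decision_formulation <- function(problem, e1, e2, t) {
  ids <- problem$subset$ids[c(e1, e2)]
  props <- if (ids[1L] == ids[2L]) stats::setNames(1, ids[1L]) else
    stats::setNames(c(t, 1 - t), ids)
  props <- props[props > 0]
  if (length(props) == 0L) props <- stats::setNames(1, ids[1L])
  make_formulation(problem$api_id, problem$api_loading, props,
                   disintegrant_id = problem$disintegrant_id,
                   lubricant_id = problem$lubricant_id,
                   disintegrant_frac = problem$disintegrant_frac,
                   lubricant_frac = problem$lubricant_frac)
}

#' Evaluate one formulation candidate
#'
#' Builds the candidate blend, predicts FFC, porosity and tensile strength
#' at the candidate pressure, and computes the robust objective and
#' constraint margins: `J = -FFC`,
#' `g_sigma = theta_sigma - (E(sigma) - alpha * delta_sigma)` and
#' `g_eps = theta_eps - (E(eps) - beta * delta_eps)`. The candidate is
#' feasible iff both margins are negative.
#'
#' @param x decision list or vector: excipient indices `e1`, `e2` into the
#'   problem subset, simplex coordinate `t` in `[0, 1]` splitting the
#'   available mass (`w1 = t * W`, `w2 = (1 - t) * W`), and initial
#'   pressure `P0` in MPa.
#' @param problem a [formulation_problem()].
#' @return list with `J`, `g_sigma`, `g_eps`, `feasible` and a
#'   `diagnostics` list (formulation, predictions).
#' @export
evaluate_candidate <- function(x, problem) {
  if (!is.list(x)) x <- list(e1 = x[[1L]], e2 = x[[2L]], t = x[[3L]], P0 = x[[4L]])
  K <- length(problem$subset$ids)
  stopifnot(x$e1 >= 1, x$e1 <= K, x$e2 >= 1, x$e2 <= K,
            x$t >= 0, x$t <= 1,
            x$P0 >= problem$P_bounds[1L], x$P0 <= problem$P_bounds[2L])
  if (K > 1L && x$e1 == x$e2) stop("excipient indices must be distinct")
  f <- decision_formulation(problem, x$e1, x$e2, x$t)
  pt <- predict_tablet(problem$models, f, problem$lib, x$P0)
  cc <- problem$constraints
  g_sigma <- cc$theta_sigma - (pt$sigma_mean - cc$alpha * pt$sigma_std)
  g_eps <- cc$theta_eps - (pt$eps_mean - cc$beta * pt$eps_std)
  list(J = -pt$ffc, g_sigma = g_sigma, g_eps = g_eps,
       feasible = g_sigma < 0 && g_eps < 0,
       diagnostics = list(formulation = f, prediction = pt))
}

#' Optimise a tablet formulation
#'
#' Selects filler/binder 1 and 2, their mass-fraction split and the
#' initial main compression pressure by a constrained elitist genetic
#' algorithm (population 30, 50 generations by default) maximising the
#' blend FFC subject to the robust tensile-strength and porosity
#' constraints of [evaluate_candidate()]. Feasibility-first
#' (constrained-domination) selection is used; when no feasible candidate
#' exists the least-infeasible one is returned with `feasible = FALSE`
#' rather than an error. Deterministic under `seed`.
#'
#' @param problem a [formulation_problem()].
#' @param pop population size (default 30).
#' @param gens number of generations (default 50).
#' @param seed RNG seed.
#' @param constrained set `FALSE` to ignore the manufacturability
#'   constraints (diagnostics only).
#' @return object of class `formulation_opt`: `decision`
#'   (`excipient1`, `excipient2`, `w1`, `w2`, `P0`), `formulation`, `J`,
#'   `ffc`, `g_sigma`, `g_eps`, `feasible`, `population`, `seed`,
#'   `generations`.
#' @export
optimise_formulation <- function(problem, pop = 30L, gens = 50L, seed = 1L,
                                 constrained = TRUE) {
  stopifnot(inherits(problem, "formulation_problem"))
  ids <- problem$subset$ids
  K <- length(ids)
  pairs <- problem$subset$deny_pairs
  fp <- if (!is.null(pairs) && length(pairs)) {
    do.call(rbind, lapply(pairs, function(p) match(p, ids)))
  } else NULL

  eval_fn <- function(ints, reals) {
    e1 <- if (K > 1L) ints[1L] else 1L
    e2 <- if (K > 1L) ints[2L] else 1L
    r <- evaluate_candidate(list(e1 = e1, e2 = e2, t = reals[1L], P0 = reals[2L]),
                            problem)
    g <- if (constrained) c(r$g_sigma, r$g_eps) else c(-1, -1)
    list(J = r$J, g = g)
  }

  res <- ga_optimise(eval_fn,
                     n_int = if (K > 1L) 2L else 0L, int_max = K,
                     lower = c(0, problem$P_bounds[1L]),
                     upper = c(1, problem$P_bounds[2L]),
                     pop = pop, gens = gens, seed = seed,
                     distinct_ints = TRUE, forbidden_pairs = fp)

  e1 <- if (K > 1L) res$best$ints[1L] else 1L
  e2 <- if (K > 1L) res$best$ints[2L] else 1L
  t <- res$best$reals[1L]; P0 <- res$best$reals[2L]
  f <- decision_formulation(problem, e1, e2, t)
  final <- evaluate_candidate(list(e1 = e1, e2 = e2, t = t, P0 = P0), problem)
  structure(list(
    decision = list(excipient1 = ids[e1], excipient2 = ids[e2],
                    w1 = t * problem$avail, w2 = (1 - t) * problem$avail, P0 = P0),
    formulation = f, J = final$J, ffc = -final$J,
    g_sigma = final$g_sigma, g_eps = final$g_eps,
    feasible = if (constrained) final$feasible else NA,
    prediction = final$diagnostics$prediction,
    population = res$population, seed = as.integer(seed), generations = gens),
    class = "formulation_opt")
}

#' @export
print.formulation_opt <- function(x, ...) {
  cat(sprintf("<formulation_opt> %s/%s split %.2f/%.2f, P0 = %.0f MPa; FFC %.2f; %s (g_sigma %.3f, g_eps %.4f)\n",
              x$decision$excipient1, x$decision$excipient2,
              x$decision$w1, x$decision$w2, x$decision$P0, x$ffc,
              if (isTRUE(x$feasible)) "feasible" else "INFEASIBLE",
              x$g_sigma, x$g_eps))
  invisible(x)
}

#' Export an optimisation result as JSON
#'
#' @param opt a [optimise_formulation()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_optimisation_report <- function(opt, path) {
  rep <- list(decision = opt$decision,
              formulation = list(ids = opt$formulation$ids, w = opt$formulation$w),
              ffc = opt$ffc, g_sigma = opt$g_sigma, g_eps = opt$g_eps,
              feasible = opt$feasible, seed = opt$seed,
              generations = opt$generations)
  writeLines(jsonlite::toJSON(rep, digits = NA, auto_unbox = TRUE, null = "null"), path)
  invisible(path)
}
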