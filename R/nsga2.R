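# Constrained elitist genetic algorithm (NSGA-II machinery specialised to a
# single objective): constrained-domination tournament selection (feasible
# beats infeasible; infeasible compared by total violation; feasible by
# objective), simulated-binary crossover and polynomial mutation on the real
# genes, uniform crossover and random-reset mutation on the integer genes
# with swap repair for duplicate excipient picks.

ga_rank_order <- function(J, viol) {
  feas <- viol <= 0
  order(!feas, ifelse(feas, 0, viol), J)
}

# a dominates b under constrained domination?
ga_better <- function(Ja, va, Jb, vb) {
  fa <- va <= 0; fb <- vb <= 0
  if (fa && !fb) return(TRUE)
  if (!fa && fb) return(FALSE)
  if (!fa && !fb) return(va < vb)
  Ja < Jb
}

sbx_pair <- function(x1, x2, lower, upper, eta = 15) {
  u <- stats::runif(length(x1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)), (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * x1 + (1 - beta) * x2)
  c2 <- 0.5 * ((1 - beta) * x1 + (1 + beta) * x2)
  list(clamp(c1, lower, upper), clamp(c2, lower, upper))
}

poly_mutate <- function(x, lower, upper, pm, eta = 20) {
  for (i in seq_along(x)) {
    if (stats::runif(1) < pm) {
      u <- stats::runif(1)
      span <- upper[i] - lower[i]
      if (span <= 0) next
      delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1 else 1 - (2 * (1 - u))^(1 / (eta + 1))
      x[i] <- clamp(x[i] + delta * span, lower[i], upper[i])
    }
  }
  x
}

#' Single-objective constrained genetic optimiser
#'
#' Mixed-encoding elitist GA used by [optimise_formulation()]. Candidates
#' carry `n_int` integer genes (categorical choices in `1..int_max`,
#' repaired to be distinct when `distinct_ints` and `int_max > 1`) and
#' real genes in `[lower, upper]`. `eval_fn(ints, reals)` must return
#' `list(J = objective-to-minimise, g = vector of constraint values,
#' feasible iff all < 0)`.
#'
#' @param eval_fn candidate evaluator.
#' @param n_int number of integer genes.
#' @param int_max upper bound of the integer gene range.
#' @param lower,upper bounds of the real genes.
#' @param pop population size.
#' @param gens number of generations.
#' @param seed RNG seed (the run is deterministic given it).
#' @param distinct_ints require pairwise-distinct integer genes.
#' @param forbidden_pairs optional 2-column matrix of integer pairs that
#'   must not co-occur (repaired away).
#' @return list with `best` (`ints`, `reals`, `J`, `g`, `feasible`),
#'   `population` (final population data.frame) and `generations`.
#' @export
ga_optimise <- function(eval_fn, n_int, int_max, lower, upper,
                        pop = 30L, gens = 50L, seed = 1L,
                        distinct_ints = TRUE, forbidden_pairs = NULL) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed %% 2147483647L)
  n_real <- length(lower)
  nvar <- n_int + n_real
  pm <- 1 / max(nvar, 1L)

  repair_ints <- function(ints) {
    if (n_int == 0L) return(ints)
    if (distinct_ints && int_max > 1L) {
      while (anyDuplicated(ints)) {
        dup <- which(duplicated(ints))[1L]
        ints[dup] <- sample.int(int_max, 1L)
      }
    }
    if (!is.null(forbidden_pairs) && n_int >= 2L) {
      bad <- function(a, b) any((forbidden_pairs[, 1L] == a & forbidden_pairs[, 2L] == b) |
                                (forbidden_pairs[, 1L] == b & forbidden_pairs[, 2L] == a))
      guard <- 0L
      while ((bad(ints[1L], ints[2L]) ||
              (distinct_ints && int_max > 1L && ints[2L] == ints[1L])) && guard < 100L) {
        ints[2L] <- sample.int(int_max, 1L)
        guard <- guard + 1L
      }
    }
    ints
  }

  random_candidate <- function() {
    ints <- if (n_int > 0L) repair_ints(sample.int(int_max, n_int, replace = !distinct_ints || int_max < n_int)) else integer(0)
    reals <- stats::runif(n_real, lower, upper)
    list(ints = ints, reals = reals)
  }

  evaluate <- function(cand) {
    r <- eval_fn(cand$ints, cand$reals)
    viol <- sum(pmax(r$g, 0))
    c(cand, list(J = r$J, g = r$g, viol = viol))
  }

  P <- lapply(seq_len(pop), function(i) evaluate(random_candidate()))

  tournament <- function() {
    i <- sample.int(pop, 2L)
    a <- P[[i[1L]]]; b <- P[[i[2L]]]
    if (ga_better(a$J, a$viol, b$J, b$viol)) a else b
  }

  for (gen in seq_len(gens)) {
    Q <- vector("list", pop)
    k <- 0L
    while (k < pop) {
      p1 <- tournament(); p2 <- tournament()
      ints1 <- p1$ints; ints2 <- p2$ints
      if (n_int > 0L && stats::runif(1) < 0.9) {
        swap <- stats::runif(n_int) < 0.5
        tmp <- ints1[swap]; ints1[swap] <- ints2[swap]; ints2[swap] <- tmp
      }
      if (stats::runif(1) < 0.9 && n_real > 0L) {
        cx <- sbx_pair(p1$reals, p2$reals, lower, upper)
      } else {
        cx <- list(p1$reals, p2$reals)
      }
      for (child in list(list(ints = ints1, reals = cx[[1L]]),
                         list(ints = ints2, reals = cx[[2L]]))) {
        if (k >= pop) break
        ints <- child$ints
        if (n_int > 0L) {
          reset <- stats::runif(n_int) < pm
          ints[reset] <- sample.int(int_max, sum(reset), replace = TRUE)
          ints <- repair_ints(ints)
        }
        reals <- poly_mutate(child$reals, lower, upper, pm)
        k <- k + 1L
        Q[[k]] <- evaluate(list(ints = ints, reals = reals))
      }
    }
    R <- c(P, Q)
    ord <- ga_rank_order(vapply(R, `[[`, numeric(1), "J"),
                         vapply(R, `[[`, numeric(1), "viol"))
    P <- R[ord[seq_len(pop)]]
  }

  popdf <- do.call(rbind, lapply(P, function(c) {
    data.frame(t(c(c$ints, c$reals, J = c$J, viol = c$viol)))
  }))
  if (n_int > 0L) names(popdf)[seq_len(n_int)] <- paste0("int", seq_len(n_int))
  if (n_real > 0L) names(popdf)[n_int + seq_len(n_real)] <- paste0("x", seq_len(n_real))
  best <- P[[1L]]
  list(best = list(ints = best$ints, reals = best$reals, J = best$J,
                   g = best$g, feasible = best$viol <= 0),
       population = popdf, generations = gens)
}
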