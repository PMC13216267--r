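# FNV-1a hash over a serialised R object: a dependency-free content hash
# for run manifests.
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor into the low byte only (h exceeds the integer range)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit FNV prime multiply, kept exact in double precision
    lo16 <- h %% 65536
    hi16 <- (h - lo16) / 65536
    h <- ((lo16 * 16777619) %% 4294967296 +
          ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Closed-loop run configuration
#'
#' @param api_id,api_loading the formulation case.
#' @param subset excipient allow-list (character) or
#'   [excipient_subset_filter()] result.
#' @param constraints a [constraint_config()].
#' @param pibo a [pibo_config()].
#' @param pop,gens genetic-optimiser settings (defaults 30 / 50).
#' @param seed master seed for the run.
#' @param noise a [plant_noise()] for the virtual plant.
#' @return list of class `closed_loop_config`.
#' @export
closed_loop_config <- function(api_id, api_loading, subset = NULL,
                               constraints = constraint_config(),
                               pibo = pibo_config(), pop = 30L, gens = 50L,
                               seed = 1L, noise = plant_noise()) {
  structure(list(api_id = api_id, api_loading = api_loading, subset = subset,
                 constraints = constraints, pibo = pibo, pop = pop, gens = gens,
                 seed = as.integer(seed), noise = noise),
            class = "closed_loop_config")
}

#' Run the closed loop: formulate, refine, validate
#'
#' Executes the full in-silico workflow: the robust genetic formulation
#' optimisation selects the excipients, split and initial pressure; a
#' virtual material law is built for the winning blend; the PIBO agent
#' refines the compression pressure on the virtual plant; and a
#' validation tablet is made at the target-porosity pressure.
#'
#' @param config a [closed_loop_config()].
#' @param lib a [material_library()].
#' @param models a `tablet_models` interface (the trained formulator
#'   stack, or the ground-truth oracle for diagnostics).
#' @return object of class `run_manifest`: `config_hash`, `seed`,
#'   `opt` (the [optimise_formulation()] result), `pibo`
#'   (the [run_pibo()] result), `outcome` summary and per-stage `timings`
#'   (seconds).
#' @export
run_closed_loop <- function(config, lib, models) {
  stopifnot(inherits(config, "closed_loop_config"))
  subset <- config$subset
  if (is.null(subset)) subset <- excipient_subset_filter(lib)
  problem <- formulation_problem(config$api_id, config$api_loading, subset, lib,
                                 models, constraints = config$constraints)
  timings <- c(formulate = NA_real_, pibo = NA_real_)
  t0 <- proc.time()[["elapsed"]]
  opt <- optimise_formulation(problem, pop = config$pop, gens = config$gens,
                              seed = config$seed)
  timings["formulate"] <- proc.time()[["elapsed"]] - t0

  law <- make_virtual_material(opt$formulation, lib, seed = config$seed,
                               noise = config$noise)
  plant <- virtual_plant(law, seed = config$seed + 1L)
  t0 <- proc.time()[["elapsed"]]
  pibo <- run_pibo(opt$decision$P0, plant, config$pibo)
  timings["pibo"] <- proc.time()[["elapsed"]] - t0

  outcome <- list(
    formulation = stats::setNames(opt$formulation$w, opt$formulation$ids),
    P0 = opt$decision$P0, formulator_feasible = opt$feasible,
    n_experiments = pibo$n_experiments, converged = pibo$converged,
    validation = pibo$validation)
  structure(list(
    config_hash = content_hash(unclass(config)),
    seed = config$seed,
    model_type = models$type,
    opt = opt, pibo = pibo, outcome = outcome, timings = timings),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  o <- x$outcome
  cat(sprintf("<run_manifest> %s | seed %d | models: %s\n",
              x$config_hash, x$seed, x$model_type))
  cat(sprintf("  formulation: %s; P0 = %.0f MPa (%s)\n",
              paste(sprintf("%s %.1f%%", names(o$formulation), 100 * o$formulation),
                    collapse = ", "),
              o$P0, if (isTRUE(o$formulator_feasible)) "feasible" else "infeasible"))
  cat(sprintf("  PIBO: %d experiments, %s; validation porosity %.4f, tensile %.2f MPa [%s]\n",
              o$n_experiments, if (o$converged) "converged" else "not converged",
              o$validation$eps_obs, o$validation$sigma_obs,
              if (o$validation$pass) "pass" else "FAIL"))
  invisible(x)
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_closed_loop()] result.
#' @param path output file.
#' @param include_timings set `FALSE` for byte-comparable manifests.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, include_timings = TRUE) {
  o <- manifest$outcome
  rep <- list(config_hash = manifest$config_hash, seed = manifest$seed,
              model_type = manifest$model_type,
              formulation = as.list(o$formulation), P0 = o$P0,
              formulator_feasible = o$formulator_feasible,
              n_experiments = o$n_experiments, converged = o$converged,
              validation = o$validation,
              timings = if (include_timings) as.list(manifest$timings) else NULL)
  writeLines(jsonlite::toJSON(rep, digits = NA, auto_unbox = TRUE, null = "null"), path)
  invisible(path)
}

log_line <- function(...) {
  msg <- list(...)
  message(jsonlite::toJSON(c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), msg),
                           auto_unbox = TRUE))
}

cli_get <- function(argv, flag, default = NULL) {
  i <- match(flag, argv)
  if (is.na(i) || i == length(argv)) default else argv[i + 1L]
}

#' Command-line entry point
#'
#' Thin shell interface over the package functions; see
#' `inst/cli/tabletlab.R` for the Rscript wrapper. Subcommands:
#' `demo` (full synthetic closed loop), `formulate`, `pibo`, `psd-sweep`,
#' `train-models`, `make-corpus`. Common flags: `--seed`, `--config`
#' (YAML), `--out`; `pibo` honours `--target-porosity`. `--version`
#' prints the package version.
#'
#' @param argv character vector of arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit code (0 ok, 2 usage error).
#' @export
tabletlab_cli <- function(argv = character()) {
  usage <- function() {
    cat("usage: tabletlab <demo|formulate|pibo|psd-sweep|train-models|make-corpus> [--seed N] [--config FILE] [--out FILE]\n")
    2L
  }
  if ("--version" %in% argv) {
    cat(sprintf("tabletlab %s\n", as.character(utils::packageVersion("tabletlab"))))
    return(0L)
  }
  if (length(argv) == 0L) return(usage())
  cmd <- argv[1L]
  seed <- as.integer(cli_get(argv, "--seed", "1"))
  out <- cli_get(argv, "--out")
  cfg_path <- cli_get(argv, "--config")
  cfg <- if (!is.null(cfg_path)) yaml::read_yaml(cfg_path) else list()
  getc <- function(name, default) if (!is.null(cfg[[name]])) cfg[[name]] else default

  lib <- synthetic_material_library()
  tryCatch({
    switch(cmd,
      "demo" = {
        log_line(stage = "train", msg = "training formulator models")
        models <- train_formulator_models(lib,
                                          n_formulations = getc("n_formulations", 30L),
                                          seed = seed,
                                          n_members = getc("n_members", 5L))
        cc <- closed_loop_config(getc("api_id", "API_C"), getc("api_loading", 0.2),
                                 seed = seed)
        manifest <- run_closed_loop(cc, lib, models)
        print(manifest)
        if (!is.null(out)) write_manifest(manifest, out)
        if (isTRUE(manifest$outcome$validation$pass)) 0L else 1L
      },
      "formulate" = {
        models <- ground_truth_tablet_models()
        subset <- excipient_subset_filter(lib,
                                          allow = getc("subset", NULL),
                                          deny = getc("deny", NULL),
                                          deny_pairs = getc("deny_pairs", NULL))
        cc <- constraint_config(theta_sigma = getc("theta_sigma", 2),
                                theta_eps = getc("theta_eps", 0.15),
                                alpha = getc("alpha", 0.2),
                                beta = getc("beta", 0.2))
        problem <- formulation_problem(getc("api_id", "API_C"),
                                       getc("api_loading", 0.2),
                                       subset, lib, models, constraints = cc,
                                       P_bounds = c(getc("p_min", 50),
                                                    getc("p_max", 400)))
        opt <- optimise_formulation(problem, pop = getc("pop", 30L),
                                    gens = getc("gens", 50L), seed = seed)
        print(opt)
        if (!is.null(out)) write_optimisation_report(opt, out)
        0L
      },
      "pibo" = {
        target <- as.numeric(cli_get(argv, "--target-porosity",
                                     as.character(getc("target_eps", 0.15))))
        f <- make_formulation(getc("api_id", "API_C"), getc("api_loading", 0.2),
                              c(MCC_A = 0.5, LAC_A = 0.5))
        noise <- plant_noise(porosity_sd = getc("porosity_sd", 0.005),
                             tensile_rel_sd = getc("tensile_rel_sd", 0.05),
                             dose_rel_sd = getc("dose_rel_sd", 0.02))
        law <- make_virtual_material(f, lib, seed = seed, noise = noise)
        plant <- virtual_plant(law, seed = seed)
        run <- run_pibo(getc("P0", 200), plant, pibo_config(target_eps = target))
        print(run)
        if (!is.null(out)) write_pibo_report(run, out)
        0L
      },
      "psd-sweep" = {
        res <- run_psd_sweep(psd_sweep_config(), ground_truth_tablet_models(), lib)
        print(trend_report(res))
        if (!is.null(out)) write_sweep_csv(res, out)
        0L
      },
      "train-models" = {
        models <- train_formulator_models(lib,
                                          n_formulations = getc("n_formulations", 70L),
                                          seed = seed,
                                          n_members = getc("n_members", 20L))
        if (!is.null(out)) save_model_bundle(models, out)
        log_line(stage = "train", msg = "model bundle trained",
                 out = if (is.null(out)) "" else out)
        0L
      },
      "make-corpus" = {
        corpus <- generate_training_corpus(lib, getc("n_formulations", 50L),
                                           getc("pressures", seq(100, 400, 50)),
                                           seed = seed)
        print(corpus)
        if (!is.null(out)) write_corpus_csv(corpus, out)
        0L
      },
      usage())
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}
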