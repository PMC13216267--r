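test_that("formulation construction and the standard recipe behave", {
  f <- make_formulation("API_A", 0.2, c(MCC_A = 1, LAC_A = 1))
  expect_equal(sum(f$w), 1, tolerance = 1e-12)
  expect_equal(f$api_loading, 0.2)
  # fixed components at their conventional levels
  expect_equal(f$w[f$ids == "CCS_SYN"], 0.035)
  expect_equal(f$w[f$ids == "MGST_SYN"], 0.01)
  # equal split of the remaining mass
  expect_equal(f$w[f$ids == "MCC_A"], (1 - 0.2 - 0.045) / 2)

  pure <- make_formulation("API_A", 1, c(MCC_A = 1))
  expect_identical(pure$ids, "API_A")
  placebo <- make_formulation(NULL, 0, c(MCC_A = 1))
  expect_null(placebo$api_id)
  expect_equal(placebo$api_loading, 0)

  expect_error(formulation(c("a", "b"), c(0.6, 0.5)), "sum")
  expect_error(formulation(c("a", "b"), c(0.5, 0.5), "c"), "not a component")
})

test_that("density mixing follows the inverse mass-weighted harmonic mean", {
  lib <- tl_lib()
  g <- default_size_grid()
  psd <- lognormal_psd(psd_spec("unimodal", 50, 1.8), g)
  ard <- tabletlab:::synthetic_ard(0.5, 8, default_aspect_grid())
  mk <- function(id, tr, bu, ta) material_record(id, "filler_binder", tr, bu, ta, psd, ard)
  lib2 <- material_library(list(mk("a", 1.0, 0.4, 0.5), mk("b", 2.0, 0.6, 0.7)))

  # hand arithmetic of the stated formula
  f <- formulation(c("a", "b"), c(0.5, 0.5))
  expect_equal(mix_true_density(f, lib2), 1 / (0.5 / 1 + 0.5 / 2), tolerance = 1e-12)
  bt <- mix_bulk_tapped(f, lib2)
  expect_equal(unname(bt["bulk"]), 1 / (0.5 / 0.4 + 0.5 / 0.6), tolerance = 1e-12)
  expect_equal(unname(bt["tapped"]), 1 / (0.5 / 0.5 + 0.5 / 0.7), tolerance = 1e-12)

  # single component reduces to identity
  f1 <- formulation("a", 1)
  expect_equal(mix_true_density(f1, lib2), 1.0)
  expect_equal(unname(mix_bulk_tapped(f1, lib2)), c(0.4, 0.5))

  # unknown component errors
  expect_error(mix_true_density(formulation("zz", 1), lib2), "not in library")

  # property sweep: bounds, ordering, permutation invariance
  set.seed(11)
  ids <- names(lib)
  for (i in 1:200) {
    pick <- sample(ids, 3)
    w <- as.numeric(rmultinom(1, 100, rep(1, 3))) / 100
    if (any(w == 0)) next
    api <- pick[vapply(pick, function(id) lib[[id]]$role == "api", logical(1))]
    f <- formulation(pick, w, if (length(api)) api[1] else NULL)
    rho <- vapply(pick, function(id) lib[[id]]$true_density, numeric(1))
    m <- mix_true_density(f, lib)
    expect_true(m >= min(rho) - 1e-12 && m <= max(rho) + 1e-12)
    bt <- mix_bulk_tapped(f, lib)
    expect_lte(bt[["bulk"]], bt[["tapped"]])
    expect_gte(m, bt[["bulk"]])
    # permutation invariance
    p <- sample(3)
    fp <- formulation(pick[p], w[p], if (length(api)) api[1] else NULL)
    expect_equal(mix_true_density(fp, lib), m, tolerance = 1e-12)
    expect_equal(mix_distribution(fp, lib, "psd")$density,
                 mix_distribution(f, lib, "psd")$density, tolerance = 1e-12)
  }
})

test_that("distribution mixing is mass-weighted and conserves mass", {
  g <- default_size_grid()
  psd_a <- lognormal_psd(psd_spec("unimodal", 10, 1.4), g)
  psd_b <- lognormal_psd(psd_spec("unimodal", 300, 1.4), g)
  ard <- tabletlab:::synthetic_ard(0.5, 8, default_aspect_grid())
  mk <- function(id, psd) material_record(id, "filler_binder", 1.5, 0.4, 0.5, psd, ard)
  lib2 <- material_library(list(mk("fine", psd_a), mk("coarse", psd_b)))

  f <- formulation(c("fine", "coarse"), c(0.5, 0.5))
  mixed <- mix_distribution(f, lib2, "psd")
  expect_equal(sum(bin_masses(mixed)), 1, tolerance = 1e-9)
  # disjoint unimodals: each mode carries half the mass
  expect_equal(mass_below(mixed, 70), 0.5, tolerance = 1e-4)
  expect_equal(mixed$density, 0.5 * psd_a$density + 0.5 * psd_b$density,
               tolerance = 1e-12)
  # identity for a pure component
  expect_equal(mix_distribution(formulation("fine", 1), lib2, "psd")$density,
               psd_a$density)

  # d50 of an overlapping mixture lies between the component medians
  psd_c <- lognormal_psd(psd_spec("unimodal", 40, 2.0), g)
  lib3 <- material_library(list(mk("a", psd_a), mk("c", psd_c)))
  m <- mix_distribution(formulation(c("a", "c"), c(0.5, 0.5)), lib3, "psd")
  d50 <- summarize_psd(m)$d50
  expect_true(d50 > summarize_psd(psd_a)$d50 && d50 < summarize_psd(psd_c)$d50)
})

test_that("flow regime classification uses the standard Jenike boundaries", {
  expect_identical(classify_flow_regime(1.2), "very_cohesive")
  expect_identical(classify_flow_regime(2.0), "cohesive")  # strict < 2
  expect_identical(classify_flow_regime(3.9), "cohesive")
  expect_identical(classify_flow_regime(6.5), "easy_flowing")
  expect_identical(classify_flow_regime(10), "free_flowing")
  expect_error(classify_flow_regime(0), "positive")
})

test_that("FFC prediction requires a trained model and anchors pure components", {
  lib <- tl_lib()
  f <- tl_demo_formulation()
  expect_error(predict_ffc(f, lib, list()), "train_ffc_surrogate")

  model <- tl_ffc_model()
  # pure-component predictions recover the anchored measured values
  for (id in c("MCC_A", "LAC_A", "MAN_A")) {
    fp <- formulation(id, 1)
    pr <- predict_ffc(fp, lib, model)
    expect_lt(abs(pr$ffc - lib[[id]]$ffc_measured) / lib[[id]]$ffc_measured, 0.05)
    expect_gte(pr$ffc_std, 0)
    expect_equal(pr$consolidation_kPa, 1.6)
  }

  # monotone response: loading up the finest API lowers FFC
  apis <- names(lib)[vapply(lib, function(r) r$role == "api", logical(1))]
  d50s <- vapply(apis, function(id) summarize_psd(lib[[id]]$psd, warn = FALSE)$d50,
                 numeric(1))
  fine_api <- apis[which.min(d50s)]
  fine_heavy <- make_formulation(fine_api, 0.6, c(MCC_A = 0.5, LAC_A = 0.5))
  fine_light <- make_formulation(fine_api, 0.1, c(MCC_A = 0.5, LAC_A = 0.5))
  expect_lt(ground_truth_ffc(fine_heavy, lib), ground_truth_ffc(fine_light, lib))
  expect_lt(predict_ffc(fine_heavy, lib, model)$ffc,
            predict_ffc(fine_light, lib, model)$ffc)
})

test_that("blend report includes properties and flow classification", {
  lib <- tl_lib()
  f <- tl_demo_formulation()
  props <- blend_properties(f, lib, tl_ffc_model())
  expect_true(props$bulk_density <= props$tapped_density)
  expect_true(props$tapped_density <= props$true_density)
  expect_true(props$ffc > 0)
  expect_true(props$flow_regime %in% c("very_cohesive", "cohesive", "easy_flowing", "free_flowing"))
  path <- file.path(tempdir(), "blend.json")
  write_blend_report(f, props, path)
  rep <- jsonlite::fromJSON(path)
  expect_equal(rep$ffc, props$ffc, tolerance = 1e-12)
  expect_equal(sum(rep$formulation$fractions), 1, tolerance = 1e-9)
})
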