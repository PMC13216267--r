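test_that("ground-truth laws are deterministic, valid and monotone in loading", {
  lib <- tl_lib()
  f <- tl_demo_formulation()
  a <- make_virtual_material(f, lib, seed = 7)
  b <- make_virtual_material(f, lib, seed = 7)
  expect_identical(unclass(a$params), unclass(b$params))
  expect_false(identical(a$params$That,
                         make_virtual_material(f, lib, seed = 8)$params$That))

  # placebo out-compacts a heavily loaded poorly-bonding API
  lib_bonds <- vapply(names(lib), function(id) {
    r <- lib[[id]]
    if (r$role == "api") r$descriptors[1] else NA_real_
  }, numeric(1))
  weak_api <- names(which.min(lib_bonds))
  placebo <- make_formulation(NULL, 0, c(MCC_A = 1, LAC_A = 1))
  loaded <- make_formulation(weak_api, 0.8, c(MCC_A = 1, LAC_A = 1))
  expect_gt(make_virtual_material(placebo, lib)$params$That,
            make_virtual_material(loaded, lib)$params$That)

  # parameter invariants over many random formulations
  set.seed(31)
  apis <- names(lib)[vapply(lib, function(r) r$role == "api", logical(1))]
  fbs <- names(lib)[vapply(lib, function(r) r$role == "filler_binder", logical(1))]
  for (i in 1:200) {
    f <- make_formulation(sample(apis, 1), runif(1, 0, 0.9),
                          setNames(runif(2), sample(fbs, 2)))
    law <- make_virtual_material(f, lib, seed = i)
    p <- law$params
    expect_true(p$eps0 > 0 && p$eps0 < 1 && p$B > 0 && p$That > 0 && p$kb > 0)
    expect_gt(law$ffc_true, 0)
  }
})

test_that("noise-free observations reproduce the compaction laws exactly", {
  lib <- tl_lib()
  law <- make_virtual_material(tl_demo_formulation(), lib, noise = noiseless())
  plant <- virtual_plant(law, seed = 1)
  obs <- observe_tablet(plant, 250)
  expect_true(obs$accepted_d1)
  expect_equal(obs$dose_weight, 250)
  expect_equal(obs$porosity, kawakita_porosity(250, law$params), tolerance = 1e-12)
  expect_equal(obs$tensile, rd_tensile(obs$porosity, law$params), tolerance = 1e-12)
  expect_error(observe_tablet(plant, 1e4), "outside press bounds")

  # a noiseless (P, eps, sigma) sweep is fitted exactly: the loop closes
  P <- seq(100, 400, 50)
  eps <- vapply(P, function(p) observe_tablet(plant, p)$porosity, numeric(1))
  sig <- vapply(P, function(p) observe_tablet(plant, p)$tensile, numeric(1))
  kf <- fit_kawakita(P, eps)
  rf <- fit_rd(eps, sig)
  expect_equal(kf$eps0, law$params$eps0, tolerance = 1e-6)
  expect_equal(rf$kb, law$params$kb, tolerance = 1e-6)
  expect_lt(kf$err_k + rf$err_rd, 1e-9)
})

test_that("gate D1 acceptance matches the normal-CDF prediction", {
  lib <- tl_lib()
  law <- make_virtual_material(tl_demo_formulation(), lib)  # dose noise 2%
  plant <- virtual_plant(law, seed = 77)
  acc <- logical(10000)
  for (i in seq_len(10000)) acc[i] <- observe_tablet(plant, 200)$accepted_d1
  predicted <- pnorm(0.05 / 0.02) - pnorm(-0.05 / 0.02)  # 0.98758
  expect_equal(mean(acc), predicted, tolerance = 0.01)
})

test_that("gate D2 tracks rolling batch means within five percent", {
  lib <- tl_lib()
  law <- make_virtual_material(tl_demo_formulation(), lib, noise = noiseless())
  plant <- virtual_plant(law, seed = 5)
  first <- observe_tablet(plant, 200)
  expect_true(first$accepted_d2)  # no history yet
  again <- observe_tablet(plant, 200)
  expect_true(again$accepted_d2)  # identical to batch mean
  # a very different pressure shifts porosity beyond 5% of the batch mean
  far <- observe_tablet(plant, 400)
  expect_false(far$accepted_d2)
})

test_that("training corpora are reproducible with valid records", {
  corpus <- tl_corpus()
  expect_equal(length(corpus$records), 86L * 7L)
  eps <- vapply(corpus$records, `[[`, numeric(1), "porosity")
  expect_true(all(eps > 0 & eps < 1))
  sig <- vapply(corpus$records, `[[`, numeric(1), "tensile")
  expect_true(all(sig > 0))
  # bit-identical regeneration under the seed
  again <- generate_training_corpus(tl_lib(), 86L, seq(100, 400, 50), seed = 42L)
  expect_identical(corpus$records[[10]]$features, again$records[[10]]$features)
  expect_identical(eps, vapply(again$records, `[[`, numeric(1), "porosity"))
  # cardinality scales as formulations x pressures
  small <- generate_training_corpus(tl_lib(), 10L, c(100, 200, 300, 400), seed = 1L)
  expect_equal(length(small$records), 40L)
  path <- file.path(tempdir(), "corpus.csv")
  write_corpus_csv(small, path)
  expect_equal(nrow(utils::read.csv(path)), 40L)
})

test_that("simulated spectra are deterministic templates plus noise", {
  lib <- tl_lib()
  f <- tl_demo_formulation()
  clean <- simulate_spectra(f, lib, 5, noise_sd = 0, weight_rel_sd = 0, seed = 1)
  expect_equal(dim(clean), c(5L, 128L))
  # zero noise, no contamination: identical rows
  expect_equal(max(abs(sweep(clean, 2, clean[1, ]))), 0)
  # contamination of sample 3 changes only that row
  cont <- simulate_spectra(f, lib, 5, noise_sd = 0, weight_rel_sd = 0,
                           contamination = 3, seed = 1)
  expect_equal(cont[1, ], clean[1, ])
  expect_gt(max(abs(cont[3, ] - clean[3, ])), 0)
  # band templates are stable functions of the material id
  t1 <- tabletlab:::material_band_template("MCC_A", 128)
  t2 <- tabletlab:::material_band_template("MCC_A", 128)
  expect_identical(t1, t2)
  expect_false(identical(t1, tabletlab:::material_band_template("LAC_A", 128)))
})

test_that("Hotelling T2 monitoring is calibrated and catches outliers", {
  lib <- tl_lib()
  f <- tl_demo_formulation()
  ref <- simulate_spectra(f, lib, 200, noise_sd = 0.002, seed = 10)
  # the training mean spectrum scores T2 = 0
  res0 <- hotelling_t2(rbind(colMeans(ref)), n_pcs = 3, reference = ref)
  expect_lt(res0$t2, 1e-9)
  expect_false(res0$flag)

  # false-flag rate over homogeneous samples approximates alpha
  new <- simulate_spectra(f, lib, 10000, noise_sd = 0.002, seed = 11)
  res <- hotelling_t2(new, n_pcs = 3, alpha_level = 0.01, reference = ref)
  expect_lt(abs(mean(res$flag) - 0.01), 0.01)

  # a strongly contaminated sample exceeds the limit
  bad <- simulate_spectra(f, lib, 20, noise_sd = 0.002, contamination = 7,
                          contamination_strength = 0.25, seed = 12)
  resb <- hotelling_t2(bad, n_pcs = 3, reference = ref)
  expect_true(resb$flag[7])
  expect_error(hotelling_t2(ref[1:3, ], n_pcs = 3), "at least")
  # rank-deficient reference reduces the component count with a warning
  flat <- matrix(rep(ref[1, ], 10), 10, byrow = TRUE) +
    matrix(rnorm(10) %o% ref[2, ] * 1e-3, 10)
  expect_warning(hotelling_t2(flat, n_pcs = 5), "reducing n_pcs")
})

test_that("the FFC surrogate recovers the ground-truth flow rule", {
  lib <- tl_lib()
  model <- tl_ffc_model()
  # held-out random blends against the noiseless rule
  set.seed(17)
  apis <- names(lib)[vapply(lib, function(r) r$role == "api", logical(1))]
  fbs <- names(lib)[vapply(lib, function(r) r$role == "filler_binder", logical(1))]
  truth <- pred <- numeric(80)
  for (i in 1:80) {
    f <- make_formulation(sample(apis, 1), runif(1, 0, 0.8),
                          setNames(runif(2), sample(fbs, 2)))
    truth[i] <- ground_truth_ffc(f, lib)
    pred[i] <- predict_ffc(f, lib, model)$ffc
  }
  expect_gte(r2_of(log(truth), log(pred)), 0.9)
  expect_error(train_ffc_surrogate(lib, n = 10), "at least 50")
  # seed determinism
  m2 <- train_ffc_surrogate(lib, n = 60, seed = 5, n_members = 2, hidden = c(16, 16))
  m3 <- train_ffc_surrogate(lib, n = 60, seed = 5, n_members = 2, hidden = c(16, 16))
  f <- tl_demo_formulation()
  expect_identical(predict_ffc(f, lib, m2)$ffc, predict_ffc(f, lib, m3)$ffc)
})
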