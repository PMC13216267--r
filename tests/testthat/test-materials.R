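test_that("size grids and binned distributions enforce their invariants", {
  expect_error(size_grid(c(1)), "at least 2")
  expect_error(size_grid(c(2, 1)), "strictly increasing")
  expect_error(size_grid(c(-1, 2)), "positive")
  g <- size_grid(c(1, 10, 100))
  expect_error(binned_dist(g, c(0.1)), "one value per bin")
  expect_error(binned_dist(g, c(-0.1, 0.2)), "non-negative")
  expect_error(binned_dist(g, c(0, 0)), "zero total mass")
  # integral slightly off within tolerance is silently renormalised
  d <- binned_dist(g, c(0.5 / 9, 0.5 / 90) * (1 + 5e-7))
  expect_equal(sum(d$density * diff(d$edges)), 1, tolerance = 1e-12)
  # beyond tolerance is rejected
  expect_error(binned_dist(g, c(0.1, 1 / 90)), "deviates from 1")
})

test_that("log-normal PSD generation hits the requested median and mixes linearly", {
  g <- default_size_grid()
  d <- lognormal_psd(psd_spec("unimodal", 10, 1.8), g)
  q <- summarize_psd(d)
  # median recovered within the local bin resolution
  edges <- as.numeric(g)
  bin_ratio <- exp(diff(log(edges))[findInterval(10, edges)])
  expect_lt(abs(log(q$d50 / 10)), log(bin_ratio))
  expect_equal(sum(bin_masses(d)), 1, tolerance = 1e-9)

  # bimodal with identical components collapses to the unimodal output
  bi <- lognormal_psd(psd_spec("bimodal", c(10, 10), c(1.8, 1.8), c(0.5, 0.5)), g)
  expect_equal(bi$density, d$density, tolerance = 1e-12)
  # weight 1/0 equals the first component alone
  bi10 <- lognormal_psd(psd_spec("bimodal", c(10, 60), c(1.8, 1.5), c(1, 0) + c(-1e-12, 1e-12)), g)
  expect_equal(bi10$density, d$density, tolerance = 1e-6)

  # weight-linearity: mixture of outputs == output of mixture spec, bin-wise
  a <- lognormal_psd(psd_spec("unimodal", 8, 1.6), g)
  b <- lognormal_psd(psd_spec("unimodal", 90, 2.0), g)
  mix <- lognormal_psd(psd_spec("bimodal", c(8, 90), c(1.6, 2.0), c(0.3, 0.7)), g)
  expect_equal(mix$density, 0.3 * a$density + 0.7 * b$density, tolerance = 1e-12)

  # truncation loss beyond 1% errors with advice
  narrow <- size_grid(exp(seq(log(5), log(20), length.out = 11)))
  expect_error(lognormal_psd(psd_spec("unimodal", 10, 2.5), narrow), "span")
})

test_that("PSD summary matches closed-form log-normal quantiles", {
  g <- default_size_grid(256L)
  sg <- 1.9
  d <- lognormal_psd(psd_spec("unimodal", 20, sg), g)
  q <- summarize_psd(d)
  z90 <- qnorm(0.9)
  span_exact <- (sg^z90 - sg^(-z90)) / 1
  expect_equal(q$span, span_exact, tolerance = 0.01)
  expect_equal(q$d10, 20 * sg^(-z90), tolerance = 0.01 * 20 * sg^(-z90) + 0.05)
  expect_true(q$d10 <= q$d50 && q$d50 <= q$d90)

  # all mass in one bin: degenerate summary with warning
  one <- dist_from_masses(c(1, 2, 4, 8), c(0, 1, 0))
  expect_warning(qq <- summarize_psd(one), "single bin")
  expect_equal(qq$span, 0)
  expect_equal(qq$d10, qq$d90)
})

test_that("distribution PCA reproduces an independent eigendecomposition", {
  g <- default_size_grid()
  set.seed(7)
  dists <- lapply(1:12, function(i) {
    lognormal_psd(psd_spec("unimodal", runif(1, 15, 120), runif(1, 1.5, 2.2)), g)
  })
  basis <- fit_distribution_pca(dists, 3L)
  X <- do.call(rbind, lapply(dists, `[[`, "density"))

  # oracle: brute-force eigendecomposition of the covariance matrix
  Xc <- sweep(X, 2, colMeans(X))
  eig <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  for (k in 1:3) {
    # components match up to sign
    expect_equal(abs(sum(basis$components[, k] * eig$vectors[, k])), 1, tolerance = 1e-6)
  }
  expect_equal(basis$explained_variance_ratio,
               (eig$values / sum(pmax(eig$values, 0)))[1:3], tolerance = 1e-6)

  # scores from projection match mean-centred inner products
  sc <- project_distribution(dists[[4]], basis)
  expect_equal(sc, as.numeric(crossprod(basis$components, X[4, ] - colMeans(X))),
               tolerance = 1e-12)

  # mean distribution projects to the origin; mean + component1 to (1,0,0)
  mean_d <- dist_from_masses(basis$edges, basis$mean * diff(basis$edges))
  expect_equal(project_distribution(mean_d, basis), c(0, 0, 0), tolerance = 1e-9)
  shifted <- structure(list(edges = basis$edges,
                            density = basis$mean + basis$components[, 1]),
                       class = "binned_dist")
  expect_equal(project_distribution(shifted, basis), c(1, 0, 0), tolerance = 1e-9)

  # full-rank reconstruction is exact, and error is non-increasing in k
  full <- fit_distribution_pca(dists, 11L)
  errs <- vapply(1:6, function(k) {
    bk <- fit_distribution_pca(dists, k)
    sum(vapply(dists, function(d) {
      rec <- reconstruct_distribution(project_distribution(d, bk), bk)
      sum((rec - d$density)^2)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
  rec <- reconstruct_distribution(project_distribution(dists[[1]], full), full)
  expect_lt(sum((rec - dists[[1]]$density)^2), 1e-9)

  # degenerate: identical distributions flagged, scores zero
  same <- rep(dists[1], 5)
  expect_warning(db <- fit_distribution_pca(same, 3L), "degenerate")
  expect_true(db$degenerate)
  expect_equal(project_distribution(dists[[1]], db), c(0, 0, 0), tolerance = 1e-9)

  # mismatched grids are rejected
  other <- lognormal_psd(psd_spec("unimodal", 30, 1.8), default_size_grid(48L))
  expect_error(fit_distribution_pca(c(dists[1:4], list(other)), 3L), "common grid")
  expect_error(project_distribution(other, basis), "grid")
})

test_that("material records validate densities, FFC and descriptors", {
  g <- default_size_grid()
  psd <- lognormal_psd(psd_spec("unimodal", 50, 1.8), g)
  ard <- tabletlab:::synthetic_ard(0.5, 8, default_aspect_grid())
  ok <- material_record("X", "filler_binder", 1.5, 0.4, 0.5, psd, ard)
  expect_s3_class(ok, "material_record")
  expect_error(material_record("X", "filler_binder", 1.5, 0.6, 0.5, psd, ard),
               "bulk <= tapped <= true")
  expect_error(material_record("X", "filler_binder", 1.5, 0.4, 0.5, psd, ard,
                               ffc_measured = -1), "positive")
  expect_error(material_record("X", "api", 1.5, 0.4, 0.5, psd, ard,
                               descriptors = 1:5), "9")
  expect_error(material_record("X", "filler_binder", 1.5, 0.4, 0.5, psd, ard,
                               descriptors = rep(0, 9)), "must not carry")
})

test_that("material libraries round-trip losslessly through CSV and JSON", {
  lib <- tl_lib()
  # build a 32-record library by jittering the synthetic one
  recs <- unclass(lib)
  base <- recs[!vapply(recs, function(r) r$role == "api", logical(1))]
  i <- 0L
  while (length(recs) < 32L) {
    i <- i + 1L
    r <- base[[(i - 1L) %% length(base) + 1L]]
    r$id <- sprintf("%s_v%d", r$id, i)
    r$true_density <- r$true_density * (1 + 0.001 * i)
    recs[[r$id]] <- r
  }
  big <- material_library(recs[1:32])
  for (ext in c("csv", "json")) {
    path <- file.path(tempdir(), paste0("lib32.", ext))
    save_material_library(big, path)
    back <- load_material_library(path)
    expect_identical(names(back), names(big))
    for (id in names(big)) {
      expect_identical(back[[id]]$role, big[[id]]$role)
      expect_identical(back[[id]]$true_density, big[[id]]$true_density)
      expect_identical(back[[id]]$psd$density, big[[id]]$psd$density)
      expect_identical(back[[id]]$ard$edges, big[[id]]$ard$edges)
      expect_identical(back[[id]]$descriptors, big[[id]]$descriptors)
      expect_identical(back[[id]]$ffc_measured, big[[id]]$ffc_measured)
    }
  }
  expect_error(load_material_library(file.path(tempdir(), "nope.csv")), "exist")
})

test_that("library schema errors name the offending record and field", {
  lib <- tl_lib()
  path <- file.path(tempdir(), "broken.csv")
  save_material_library(lib, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(descriptors = "character"))
  df$psd_edges[2] <- ""
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(load_material_library(path), "psd_edges")
})
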