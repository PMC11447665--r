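shap_fixture <- function(k = 3, weights = c(0.5, -0.3, 0.2), intercept = 0.4,
                         seed = 17) {
  g <- seq(400, 1200, by = 2)
  zs <- even_zones(g, k)
  set.seed(seed)
  x <- spectrum(g, runif(length(g), 0, 1))
  list(grid = g, zs = zs, x = x,
       model = toy_zone_model(weights, zs, intercept = intercept),
       weights = weights)
}

test_that("exact Shapley values obey dummy, single-zone, and closed forms", {
  fx <- shap_fixture()
  cm <- constant_model(c(0.25, 0.75))
  a0 <- exact_zone_shap(cm, fx$x, fx$zs, baseline = "zero")
  expect_equal(a0$values, rep(0, 3), tolerance = 1e-12)

  one <- zone_set(1L, length(fx$grid), fx$grid)
  m1 <- toy_zone_model(0.6, one, intercept = 0.1)
  a1 <- exact_zone_shap(m1, fx$x, one, baseline = "zero", class_index = 1)
  fx_all <- predict_proba(m1, fx$x$intensities)[1, 1]
  fx_none <- predict_proba(m1, numeric(length(fx$grid)))[1, 1]
  expect_equal(a1$values, unname(fx_all - fx_none), tolerance = 1e-12)

  # linear zone-mean model, zero baseline: phi_i = w_i * mean_i(x)
  a <- exact_zone_shap(fx$model, fx$x, fx$zs, baseline = "zero")
  closed <- fx$weights * drop(zone_means(fx$zs, fx$x$intensities))
  expect_equal(a$values, closed, tolerance = 1e-9)

  # and equals an independent brute-force subset enumeration
  oracle <- oracle_shap(fx$model, fx$x, fx$zs,
                        background = numeric(length(fx$grid)), class_index = 1)
  expect_equal(a$values, oracle, tolerance = 1e-9)
})

test_that("exact Shapley values satisfy efficiency and symmetry", {
  g <- seq(400, 1198, by = 2) # 400 points, splits evenly in 2 and 4
  zs <- even_zones(g, 4)
  # nonlinear in zone means so efficiency is not trivially linear
  m <- model_adapter(function(X) {
    zm <- zone_means(zs, X)
    p <- stats::plogis(zm %*% c(2, -1, 1.5, 0) - 1)
    cbind(p, 1 - p)
  }, c("a", "b"))
  set.seed(4)
  x <- spectrum(g, runif(length(g)))
  ref <- random_reference(g, n = 6, seed = 2)
  a <- exact_zone_shap(m, x, zs, baseline = "reference_mean", reference = ref)
  expect_equal(sum(a$values), a$prediction - a$base_value, tolerance = 1e-9)
  # dummy axiom: the zero-weight zone contributes nothing
  expect_equal(a$values[4], 0, tolerance = 1e-9)

  # symmetry: duplicate the instance across two zones with equal weights
  zs2 <- even_zones(g, 2)
  half <- length(g) / 2
  xs <- spectrum(g, rep(x$intensities[1:half], 2))
  m2 <- toy_zone_model(c(0.3, 0.3), zs2, intercept = 0.2)
  a2 <- exact_zone_shap(m2, xs, zs2, baseline = "zero")
  expect_equal(a2$values[1], a2$values[2], tolerance = 1e-9)
})

test_that("the zone cap redirects to the sampling explainer", {
  g <- seq(400, 1200, by = 2)
  zs <- even_zones(g, 6)
  m <- toy_zone_model(rep(0.1, 6), zs, intercept = 0.2)
  x <- spectrum(g, rep(0.5, length(g)))
  expect_error(exact_zone_shap(m, x, zs, baseline = "zero", max_zones = 5),
               "sampling_zone_shap")
})

test_that("sampling Shapley matches exact enumeration within 4 standard errors", {
  g <- seq(400, 1400, by = 2)
  zs <- even_zones(g, 8)
  set.seed(8)
  w <- round(runif(8, -0.4, 0.4), 2)
  m <- model_adapter(function(X) {
    zm <- zone_means(zs, X)
    p <- stats::plogis(zm %*% w)
    cbind(p, 1 - p)
  }, c("a", "b"))
  x <- spectrum(g, runif(length(g)))
  ref <- random_reference(g, n = 10, seed = 6)
  ex <- exact_zone_shap(m, x, zs, baseline = "reference_mean", reference = ref)
  sa <- sampling_zone_shap(m, x, zs, baseline = "reference_mean",
                           reference = ref, N = 5000, seed = 100)
  expect_true(all(abs(sa$values - ex$values) < 4 * pmax(sa$se, 1e-12)))
  # efficiency holds exactly by telescoping
  expect_equal(sum(sa$values), sa$prediction - sa$base_value, tolerance = 1e-12)
  # distinct coalitions are evaluated at most once
  expect_lte(sa$n_evaluations, 2^8)
})

test_that("sampling is deterministic per seed and zero-variance on constants", {
  fx <- shap_fixture(k = 4, weights = c(0.1, 0.2, -0.1, 0.05))
  s1 <- sampling_zone_shap(fx$model, fx$x, fx$zs, baseline = "zero",
                           N = 200, seed = 5)
  s2 <- sampling_zone_shap(fx$model, fx$x, fx$zs, baseline = "zero",
                           N = 200, seed = 5)
  expect_identical(s1$values, s2$values)
  s3 <- sampling_zone_shap(fx$model, fx$x, fx$zs, baseline = "zero",
                           N = 200, seed = 6)
  expect_false(identical(s1$values, s3$values))

  cm <- constant_model(c(0.4, 0.6))
  sc <- sampling_zone_shap(cm, fx$x, fx$zs, baseline = "zero", N = 50, seed = 1)
  expect_equal(sc$values, rep(0, 4), tolerance = 1e-12)
  expect_equal(sc$se, rep(0, 4), tolerance = 1e-12)
  expect_error(sampling_zone_shap(fx$model, fx$x, fx$zs, baseline = "zero",
                                  N = 4, seed = 1), "twice the zone count")
})

test_that("sampling error shrinks roughly as N^{-1/2}", {
  g <- seq(400, 1400, by = 2)
  zs <- even_zones(g, 8)
  set.seed(12)
  w <- runif(8, -0.3, 0.3)
  m <- model_adapter(function(X) {
    p <- stats::plogis(zone_means(zs, X) %*% w)
    cbind(p, 1 - p)
  }, c("a", "b"))
  x <- spectrum(g, runif(length(g)))
  ex <- exact_zone_shap(m, x, zs, baseline = "zero")
  rmse <- vapply(c(500, 2000, 8000), function(N) {
    sa <- sampling_zone_shap(m, x, zs, baseline = "zero", N = N, seed = 77)
    sqrt(mean((sa$values - ex$values)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_gt(rmse[1] / rmse[3], 2) # ~sqrt(16) = 4 in expectation
})

test_that("dataset explanations align with per-spectrum calls and permute cleanly", {
  g <- seq(400, 1200, by = 2)
  zs <- even_zones(g, 4)
  m <- toy_zone_model(c(0.2, -0.1, 0.15, 0.05), zs, intercept = 0.3)
  ref <- random_reference(g, n = 20, seed = 15)
  ds1 <- spectra_set(g, ref$intensities[1, , drop = FALSE])
  single <- explain_dataset(m, ds1, zs, method = "exact_shap",
                            class_index = 1, seed = 3, baseline = "zero")
  direct <- exact_zone_shap(m, get_spectrum(ds1, 1), zs, baseline = "zero",
                            class_index = 1, seed = (3 + 7919) %% .Machine$integer.max)
  expect_equal(single[[1]]$values, direct$values, tolerance = 1e-12)

  atts <- explain_dataset(m, ref, zs, method = "exact_shap", class_index = 1,
                          seed = 3, baseline = "zero")
  # exact values are seed-free, so permuting rows permutes results identically
  perm <- rev(seq_len(20))
  shuffled <- spectra_set(g, ref$intensities[perm, ])
  atts_p <- explain_dataset(m, shuffled, zs, method = "exact_shap",
                            class_index = 1, seed = 3, baseline = "zero")
  for (i in seq_len(20)) {
    expect_equal(atts_p[[i]]$values, atts[[perm[i]]]$values, tolerance = 1e-12)
  }

  # mean |phi| ranking matches an oracle recomputation
  V <- t(vapply(atts, function(a) a$values, numeric(4)))
  oracle_rank <- order(-colMeans(abs(V)))
  sm <- summary_data(atts, ref)
  expect_equal(sm$zone_order, oracle_rank)
  expect_error(explain_dataset(m, random_reference(seq(400, 1200, by = 4), 3),
                               zs, method = "exact_shap"), "grid")
})
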