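test_that("generate_spectrum is deterministic and shape-exact without noise", {
  prof <- class_profile("pure", c(0, 0, 0, 0, 0, 0, 1, 0, 0), bandwidth = 10,
                        bottle_sd = 0, noise = 0, baseline_amplitude = 0)
  g <- seq(400, 3100, by = 1)
  s <- generate_spectrum(prof, g, bottle_seed = 1, measurement_seed = 1)
  expect_equal(g[which.max(s$intensities)], 1656)
  expect_equal(s$intensities, exp(-(g - 1656)^2 / (2 * 10^2)), tolerance = 1e-12)

  prof2 <- class_profile("noisy", rep(0.5, 9), noise = 0.01)
  a <- generate_spectrum(prof2, bottle_seed = 3, measurement_seed = 8)
  b <- generate_spectrum(prof2, bottle_seed = 3, measurement_seed = 8)
  expect_identical(a$intensities, b$intensities)
  c2 <- generate_spectrum(prof2, bottle_seed = 3, measurement_seed = 9)
  expect_false(identical(a$intensities, c2$intensities))

  expect_error(generate_spectrum(prof2, grid = seq(400, 1000, by = 2)),
               "outside the grid")
})

test_that("band amplitude is recoverable by a local quadratic fit", {
  prof <- class_profile("quad", c(0.3, 0, 0, 0, 0, 0, 0.8, 0, 0),
                        bandwidth = 10, bottle_sd = 0, noise = 0.005,
                        baseline_amplitude = 0)
  g <- seq(400, 3100, by = 2)
  s <- generate_spectrum(prof, g, bottle_seed = 1, measurement_seed = 4)
  # normalisation divides by the global max; undo it via the known 1656 apex
  win <- abs(g - 1656) <= 8
  fit <- lm(log(s$intensities[win]) ~ poly(g[win], 2, raw = TRUE))
  co <- unname(coef(fit))
  apex <- -co[2] / (2 * co[3])
  height <- exp(co[1] - co[2]^2 / (4 * co[3])) # vertex of the log-parabola
  scale <- max(prof$amplitudes) # clean spectrum max is the 1656 amplitude
  expect_lt(abs(height * scale - 0.8) / 0.8, 0.02)
  expect_lt(abs(apex - 1656), 2)
})

test_that("the default study design yields the 320/240 bottle-split", {
  sets <- generate_dataset(seed = 2)
  expect_equal(n_spectra(sets$train), 320)
  expect_equal(n_spectra(sets$test), 240)
  expect_equal(length(unique(sets$train$labels)), 8)
  expect_true(all(table(sets$train$batches) == 10))
  expect_true(all(table(sets$test$batches) == 10))
  # bottles never shared across the split
  expect_length(intersect(unique(sets$train$batches),
                          unique(sets$test$batches)), 0)
  profs <- oil_class_profiles()
  profs[[2]]$name <- profs[[1]]$name
  expect_error(generate_dataset(profs), "duplicate class names")
})

test_that("toy zone models expose their closed-form ground truth", {
  g <- seq(400, 1200, by = 2)
  zs <- even_zones(g, 3)
  cm <- toy_zone_model(c(0, 0, 0), zs, intercept = 0.4)
  X <- matrix(runif(3 * length(g)), 3)
  expect_true(all(predict_proba(cm, X)[, 1] == 0.4))

  w <- c(0.4, -0.2, 0.3)
  m <- toy_zone_model(w, zs, intercept = 0.5)
  set.seed(14)
  x <- spectrum(g, runif(length(g)))
  a <- exact_zone_shap(m, x, zs, baseline = "zero")
  expect_equal(a$values, w * drop(zone_means(zs, x$intensities)),
               tolerance = 1e-9)

  W <- matrix(rnorm(12), nrow = 4)
  sm <- toy_zone_model(W, zs, link = "softmax")
  P <- predict_proba(sm, X)
  expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-9)
  expect_error(toy_zone_model(c(1, 2), zs), "weight per zone")
})

test_that("the stand-in classifier is accurate, reproducible, and contract-true", {
  sets <- generate_dataset(seed = 3)
  m1 <- stand_in_classifier(sets$train, seed = 1)
  m2 <- stand_in_classifier(sets$train, seed = 1)
  expect_identical(coef(m1$fit), coef(m2$fit))
  P <- predict_proba(m1, sets$test$intensities)
  expect_equal(rowSums(P), rep(1, 240), tolerance = 1e-6)
  acc <- mean(m1$class_names[max.col(P)] == sets$test$labels)
  expect_gte(acc, 0.9)

  # separable two-class toy set trains to perfect accuracy
  g <- seq(400, 1200, by = 2)
  lo <- gaussian_spectrum(600, grid = g, sigma = 30)
  hi <- gaussian_spectrum(1000, grid = g, sigma = 30)
  M <- rbind(matrix(rep(lo$intensities, 5), 5, byrow = TRUE) +
               matrix(rnorm(5 * length(g), 0, 0.01), 5),
             matrix(rep(hi$intensities, 5), 5, byrow = TRUE) +
               matrix(rnorm(5 * length(g), 0, 0.01), 5))
  two <- spectra_set(g, M, labels = rep(c("low", "high"), each = 5))
  mt <- stand_in_classifier(two, seed = 2)
  Pt <- predict_proba(mt, two$intensities)
  expect_equal(mean(mt$class_names[max.col(Pt)] == two$labels), 1.0)
  one <- spectra_set(g, M[1:5, ], labels = rep("low", 5))
  expect_error(stand_in_classifier(one), "two classes")
})

test_that("a planted discriminating band earns the top mean attribution", {
  g <- seq(400, 1600, by = 2)
  base_bands <- c(600, 1000, 1400)
  make_class <- function(extra_amp, n, seed) {
    set.seed(seed)
    t(vapply(seq_len(n), function(i) {
      y <- gaussian_spectrum(base_bands, grid = g, sigma = 25,
                             amplitudes = c(0.8, 0.9, 0.7))$intensities
      y <- y + extra_amp * exp(-(g - 1200)^2 / (2 * 25^2))
      y + rnorm(length(g), 0, 0.01)
    }, numeric(length(g))))
  }
  M <- rbind(make_class(0.0, 12, 1), make_class(0.6, 12, 2))
  ds <- spectra_set(g, M, labels = rep(c("plain", "banded"), each = 12))
  zs <- global_zones(ds)
  m <- stand_in_classifier(ds, seed = 1, zones = zs)
  cls <- which(m$class_names == "banded")
  sub <- spectra_set(g, M[13:24, ], labels = ds$labels[13:24])
  atts <- explain_dataset(m, sub, zs, method = "exact_shap",
                          class_index = cls, baseline = "reference_mean",
                          reference = ds)
  V <- t(vapply(atts, function(a) a$values, numeric(n_zones(zs))))
  top_zone <- which.max(colMeans(abs(V)))
  expect_true(zs$zones$lo[top_zone] < 1200 && 1200 < zs$zones$hi[top_zone])
})

test_that("the full synthetic pipeline is bit-reproducible from one seed", {
  run <- function() {
    sets <- generate_dataset(seed = 11)
    zs <- global_zones(sets$train)
    m <- stand_in_classifier(sets$train, seed = 11, zones = zs)
    x <- get_spectrum(sets$test, 5)
    sampling_zone_shap(m, x, zs, baseline = "reference_mean",
                       reference = sets$train, N = 60, seed = 11)
  }
  a1 <- run(); a2 <- run()
  expect_identical(a1$values, a2$values)
  expect_identical(a1$base_value, a2$base_value)
  expect_identical(a1$prediction, a2$prediction)
})
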