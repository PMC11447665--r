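#' Raman band library for edible oils and fats
#'
#' The characteristic fatty-acid bands used by the synthetic generator:
#' C-C aliphatic stretch (760), C-H bend / trans C=C (972), cis -CH=CH-
#' in-plane deformation (1265), CH2 twist (1302), CH2 scissoring (1440),
#' O-CH3 symmetric deformation (1460), cis C=C stretch (1656), ester C=O
#' stretch (1745) and the aliphatic CH2 symmetric stretch (2843).
#'
#' @return Tibble with columns `position` (cm^-1) and `assignment`.
#' @export
band_library <- function() {
  tibble::tibble(
    position = c(760, 972, 1265, 1302, 1440, 1460, 1656, 1745, 2843),
    assignment = c("nu(C-C) aliphatic", "delta(C-H) / trans C=C",
                   "delta(=C-H) cis in-plane", "tau(CH2)", "delta(CH2)",
                   "delta(CH3) of O-CH3", "nu(C=C) cis", "nu(C=O) ester",
                   "nu_s(CH2)"))
}

#' Default synthetic wavenumber grid
#' @param from,to Range in cm^-1.
#' @param by Step in cm^-1.
#' @return Numeric grid.
#' @export
default_grid <- function(from = 400, to = 3100, by = 2) seq(from, to, by = by)

#' Define a synthetic oil class profile
#'
#' @param name Class name.
#' @param amplitudes Non-negative mean band amplitudes, one per row of
#'   [band_library()].
#' @param bandwidth Gaussian sigma of every band, cm^-1.
#' @param bottle_sd Standard deviation of the per-bottle multiplicative
#'   (log-normal) amplitude jitter emulating batch-to-batch variability.
#' @param noise Standard deviation of the i.i.d. measurement noise, relative
#'   to the (pre-normalisation) band amplitudes.
#' @param baseline_amplitude Amplitude of the smooth low-order polynomial
#'   baseline drift.
#' @return Object of class `class_profile`.
#' @export
class_profile <- function(name, amplitudes, bandwidth = 8, bottle_sd = 0.05,
                          noise = 0.005, baseline_amplitude = 0.02) {
  amplitudes <- as.numeric(amplitudes)
  stopifnot(length(amplitudes) == nrow(band_library()))
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  structure(list(name = name, amplitudes = amplitudes, bandwidth = bandwidth,
                 bottle_sd = bottle_sd, noise = noise,
                 baseline_amplitude = baseline_amplitude),
            class = "class_profile")
}

#' Stylised profiles for the eight oil classes
#'
#' Eight distinct amplitude patterns over the [band_library()] bands, shaped by
#' lipid chemistry (polyunsaturated oils strong at the cis C=C bands 1265/1656,
#' coconut dominated by the saturated CH2 bands, seed oils with a marked
#' 1460 cm^-1 shoulder) but deliberately stylised: they are not fits to any
#' measured spectra.
#'
#' @param noise Measurement-noise level shared by all classes.
#' @param bottle_sd Per-bottle amplitude jitter shared by all classes.
#' @return Named list of eight [class_profile()] objects.
#' @export
oil_class_profiles <- function(noise = 0.005, bottle_sd = 0.05) {
  ##              760   972  1265  1302  1440  1460  1656  1745  2843
  amp <- rbind(
    olive      = c(0.20, 0.25, 0.45, 0.60, 1.00, 0.30, 0.75, 0.40, 0.90),
    sunflower  = c(0.15, 0.30, 0.65, 0.50, 0.95, 0.35, 0.95, 0.45, 0.80),
    canola     = c(0.18, 0.28, 0.60, 0.55, 1.00, 0.30, 0.85, 0.40, 0.85),
    sesame     = c(0.35, 0.30, 0.55, 0.50, 0.90, 0.70, 0.80, 0.45, 0.75),
    peanut     = c(0.25, 0.22, 0.50, 0.55, 0.95, 0.50, 0.70, 0.40, 0.85),
    grape_seed = c(0.12, 0.35, 0.70, 0.45, 0.90, 0.40, 1.00, 0.50, 0.70),
    linseed    = c(0.10, 0.45, 0.85, 0.40, 0.80, 0.25, 1.10, 0.45, 0.65),
    coconut    = c(0.45, 0.15, 0.10, 0.75, 1.10, 0.20, 0.15, 0.55, 1.00))
  profs <- lapply(rownames(amp), function(nm) {
    class_profile(nm, amp[nm, ], noise = noise, bottle_sd = bottle_sd)
  })
  names(profs) <- rownames(amp)
  profs
}

#' Generate one synthetic spectrum
#'
#' Sum of Gaussian bands at the library positions with bottle-jittered
#' amplitudes, plus a smooth quadratic baseline drift and i.i.d. Gaussian
#' noise, max-normalised. Deterministic in `(bottle_seed, measurement_seed)`:
#' the bottle seed fixes the amplitude jitter (shared by all spectra of a
#' bottle), the measurement seed fixes baseline and noise.
#'
#' @param profile A [class_profile()].
#' @param grid Wavenumber grid covering every band position.
#' @param bottle_seed,measurement_seed Integer seeds.
#' @param id Spectrum id.
#' @return A [spectrum()].
#' @export
generate_spectrum <- function(profile, grid = default_grid(),
                              bottle_seed = 1L, measurement_seed = 1L,
                              id = profile$name) {
  stopifnot(inherits(profile, "class_profile"))
  pos <- band_library()$position
  active <- profile$amplitudes > 0
  if (any(active & (pos < min(grid) | pos > max(grid)))) {
    stop("band position outside the grid range [", min(grid), ", ", max(grid),
         "]", call. = FALSE)
  }
  set.seed(bottle_seed)
  jitter <- exp(stats::rnorm(length(pos), 0, profile$bottle_sd))
  amp <- profile$amplitudes * jitter
  clean <- numeric(length(grid))
  for (k in seq_along(pos)) {
    clean <- clean + amp[k] * exp(-(grid - pos[k])^2 / (2 * profile$bandwidth^2))
  }
  set.seed(measurement_seed)
  t <- (grid - min(grid)) / (max(grid) - min(grid))
  co <- stats::runif(3, -1, 1)
  baseline <- profile$baseline_amplitude * (co[1] + co[2] * t + co[3] * t^2)
  y <- clean + baseline + stats::rnorm(length(grid), 0, profile$noise)
  spectrum(grid, y / max(y), id = id)
}

#' Generate a train/test dataset emulating a bottled-oil study design
#'
#' Each class contributes `bottles_train + bottles_test` independent bottles
#' with `repeats` spectra each; the defaults (8 classes, 4 training and 3
#' testing bottles, 10 repeats) give 320 training and 240 testing spectra.
#' Bottles are split between train and test, never shared.
#'
#' @param profiles Named list of distinct [class_profile()]s.
#' @param bottles_train,bottles_test Bottles per class in each split.
#' @param repeats Spectra per bottle.
#' @param seed Master seed; all bottle and measurement seeds derive from it.
#' @param grid Wavenumber grid.
#' @return List with `train` and `test` `spectra_set`s (labels = class names,
#'   batches = bottle ids).
#' @export
generate_dataset <- function(profiles = oil_class_profiles(),
                             bottles_train = 4, bottles_test = 3,
                             repeats = 10, seed = 1L, grid = default_grid()) {
  nm <- vapply(profiles, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate class names: ",
                              paste(nm[duplicated(nm)], collapse = ", "),
                              call. = FALSE)
  build <- function(bottles) {
    rows <- list(); labels <- character(0); batches <- character(0)
    ids <- character(0)
    for (ci in seq_along(profiles)) {
      for (b in bottles) {
        bseed <- (seed * 1009L + ci * 1000L + b * 17L) %% .Machine$integer.max
        for (r in seq_len(repeats)) {
          mseed <- (bseed + 100000L + r * 97L) %% .Machine$integer.max
          s <- generate_spectrum(profiles[[ci]], grid, bseed, mseed)
          rows[[length(rows) + 1L]] <- s$intensities
          labels <- c(labels, nm[ci])
          batches <- c(batches, sprintf("%s_bottle%d", nm[ci], b))
          ids <- c(ids, sprintf("%s_b%d_m%02d", nm[ci], b, r))
        }
      }
    }
    spectra_set(grid, do.call(rbind, rows), ids = ids, labels = labels,
                batches = batches)
  }
  list(train = build(seq_len(bottles_train)),
       test = build(bottles_train + seq_len(bottles_test)))
}

#' Analytic toy model over zone means
#'
#' A model whose output depends on the input only through per-zone mean
#' intensities: with the identity link and a weight vector `w`, class 1 gets
#' probability `sum(w * zone_means)` (class 2 its complement), so the exact
#' zone Shapley value under a fixed background `b` is
#' `w_i * (mean_i(x) - mean_i(b))` in closed form. With the softmax link,
#' `weights` is an `n_classes x n_zones` matrix.
#'
#' @param weights Numeric vector (identity link, 2 classes) or matrix
#'   (softmax link).
#' @param zs A [zone_set()].
#' @param link `"identity"` or `"softmax"`.
#' @param intercept Added to the linear predictor(s).
#' @return A [model_adapter()].
#' @export
toy_zone_model <- function(weights, zs, link = c("identity", "softmax"),
                           intercept = 0) {
  link <- match.arg(link)
  stopifnot(all(is.finite(weights)))
  if (link == "identity") {
    w <- as.numeric(weights)
    if (length(w) != n_zones(zs)) stop("need one weight per zone", call. = FALSE)
    predict <- function(X) {
      p <- drop(zone_means(zs, X) %*% w) + intercept
      cbind(p, 1 - p)
    }
    model_adapter(predict, c("class_1", "class_2"), grid = zs$grid)
  } else {
    W <- as.matrix(weights)
    if (ncol(W) != n_zones(zs)) stop("weights needs n_zones columns",
                                     call. = FALSE)
    predict <- function(X) {
      eta <- zone_means(zs, X) %*% t(W) + intercept
      e <- exp(eta - apply(eta, 1, max))
      e / rowSums(e)
    }
    model_adapter(predict, paste0("class_", seq_len(nrow(W))), grid = zs$grid)
  }
}

#' Train a stand-in spectral classifier
#'
#' A deterministic multinomial logistic regression on per-zone mean
#' intensities, wrapped in the [model_adapter()] contract. It stands in for
#' whatever deep classifier a user wants explained, so the whole
#' zones-perturb-attribute-plot workflow is exercisable end to end.
#'
#' @param train Labeled `spectra_set` with at least two classes.
#' @param seed Integer seed (training is reproducible from it).
#' @param zones Optional [zone_set()]; default [global_zones()] of `train`.
#' @param decay Weight-decay regularisation passed to [nnet::multinom()].
#' @return A [model_adapter()] with extra fields `zones` and `fit`.
#' @export
stand_in_classifier <- function(train, seed = 1L, zones = NULL, decay = 1e-3) {
  stopifnot(inherits(train, "spectra_set"))
  classes <- sort(unique(train$labels[!is.na(train$labels)]))
  if (length(classes) < 2) stop("training set must contain at least two classes",
                                call. = FALSE)
  if (is.null(zones)) zones <- global_zones(train)
  feats <- zone_means(zones, train$intensities)
  df <- data.frame(.class = factor(train$labels, levels = classes), feats)
  set.seed(seed)
  fit <- nnet::multinom(.class ~ ., data = df, trace = FALSE, maxit = 500,
                        decay = decay, MaxNWts = 10000)
  predict_fn <- function(X) {
    nd <- data.frame(zone_means(zones, X))
    names(nd) <- names(df)[-1]
    P <- stats::predict(fit, newdata = nd, type = "probs")
    if (length(classes) == 2) {        # two-class multinom returns P(class 2)
      P <- cbind(1 - as.numeric(P), as.numeric(P))
    } else if (is.null(dim(P))) {      # single row returns a named vector
      P <- matrix(P, nrow = 1)
    }
    P <- matrix(as.numeric(P), nrow = nrow(nd))
    P / rowSums(P)
  }
  m <- model_adapter(predict_fn, classes, grid = train$grid)
  m$zones <- zones
  m$fit <- fit
  m
}
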