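## Coalition machinery ------------------------------------------------------
##
## A coalition S is the set of zones retained from the instance x; zones
## outside S are overwritten with a fixed background vector realising the
## replacement baseline. The background is drawn once per explanation, so a
## coalition bitmask identifies its spectrum uniquely and model calls can be
## memoized.

coalition_matrix <- function(x, zs, background, masks) {
  n <- nrow(masks)
  out <- matrix(rep(x$intensities, each = n), nrow = n)
  for (i in seq_len(n_zones(zs))) {
    idx <- zone_indices(zs, i)
    rows <- masks[, i] == 0L
    if (any(rows)) out[rows, idx] <- matrix(rep(background[idx], each = sum(rows)),
                                            nrow = sum(rows))
  }
  out
}

## masks from bitmask integers (bit i set = zone i retained)
bitmask_to_masks <- function(bm, nz) {
  m <- vapply(bm, function(b) as.integer(bitwAnd(b, bitwShiftL(1L, 0:(nz - 1))) != 0L),
              integer(nz))
  t(matrix(m, nrow = nz)) # keep orientation even for a single zone
}

new_attribution <- function(zs, values, base_value, prediction, class_index,
                            class_name, method, n_evaluations, seed = NA,
                            se = NULL, surrogate = NULL) {
  structure(list(zone_set = zs, values = as.numeric(values),
                 se = se, base_value = base_value, prediction = prediction,
                 class_index = class_index, class_name = class_name,
                 method = method, n_evaluations = n_evaluations, seed = seed,
                 surrogate = surrogate),
            class = "zone_attribution")
}

#' @export
print.zone_attribution <- function(x, ...) {
  cat(sprintf("<zone_attribution> %s, class '%s': base %.4g -> prediction %.4g, %d zones, %d model evaluations\n",
              x$method, x$class_name, x$base_value, x$prediction,
              length(x$values), x$n_evaluations))
  invisible(x)
}

resolve_class <- function(model, x, class_index) {
  p <- predict_proba(model, x$intensities)
  if (is.null(class_index)) class_index <- which.max(p[1, ])
  class_index <- check_class_index(model, class_index)
  list(class_index = class_index, fx = p[1, class_index])
}

#' Exact zone-level Shapley values
#'
#' Enumerates all `2^n` coalitions of zones. A zone inside a coalition keeps
#' its intensities from `x`; outside, it takes the baseline replacement
#' (zero, pointwise reference mean, or one seeded reference spectrum). The
#' Shapley value of zone `i` is the classic weighted average of its marginal
#' contributions over all coalitions excluding it, so the efficiency,
#' symmetry and dummy axioms hold exactly. Model calls are memoized by
#' coalition bitmask and batched.
#'
#' @param model A [model_adapter()].
#' @param x The [spectrum()] instance to explain.
#' @param zs A [zone_set()] on `x`'s grid.
#' @param baseline Replacement baseline (see [perturbation_spec()]).
#' @param reference Reference `spectra_set` for the reference baselines.
#' @param class_index Class to explain (default: the model's argmax on `x`).
#' @param seed Seed used only by the `"reference_sample"` baseline.
#' @param max_zones Enumeration cap; beyond it use [sampling_zone_shap()].
#' @return A `zone_attribution` with one value per zone, `base_value` (the
#'   model output on the fully-replaced spectrum — the explainer's estimate of
#'   the expected model output) and `prediction` (`f(x)`).
#' @export
exact_zone_shap <- function(model, x, zs, baseline = "reference_mean",
                            reference = NULL, class_index = NULL, seed = 1L,
                            max_zones = 20) {
  stopifnot(inherits(x, "spectrum"), inherits(zs, "zone_set"))
  nz <- n_zones(zs)
  if (nz > max_zones) {
    stop("zone count ", nz, " exceeds the exact-enumeration cap (", max_zones,
         "); use sampling_zone_shap()", call. = FALSE)
  }
  cl <- resolve_class(model, x, class_index)
  background <- baseline_vector(x, baseline, reference, seed)
  bm <- 0:(2^nz - 1)
  v <- numeric(length(bm))
  batch <- 2048L
  for (lo in seq(1, length(bm), by = batch)) {
    hi <- min(lo + batch - 1L, length(bm))
    M <- coalition_matrix(x, zs, background, bitmask_to_masks(bm[lo:hi], nz))
    v[lo:hi] <- predict_proba(model, M)[, cl$class_index]
  }
  pc <- popcount(bm, nz)
  ## weight of a coalition of size s (excluding zone i): s!(n-s-1)!/n!
  wt <- 1 / (nz * choose(nz - 1, 0:(nz - 1)))
  phi <- numeric(nz)
  for (i in seq_len(nz)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- bm[bitwAnd(bm, bit) == 0L]
    s <- pc[without + 1L]
    phi[i] <- sum(wt[s + 1L] * (v[without + bit + 1L] - v[without + 1L]))
  }
  new_attribution(zs, phi,
                  base_value = v[1], prediction = v[length(v)],
                  class_index = cl$class_index,
                  class_name = model$class_names[cl$class_index],
                  method = "exact_shap", n_evaluations = length(bm),
                  seed = seed)
}

popcount <- function(bm, nbits) {
  out <- integer(length(bm))
  for (b in 0:(nbits - 1)) {
    out <- out + as.integer(bitwAnd(bm, bitwShiftL(1L, b)) != 0L)
  }
  out
}

#' Monte-Carlo zone-level Shapley values by permutation sampling
#'
#' Approximates the exact enumeration when the zone count makes `2^n`
#' infeasible: for each of `N` draws a uniform random permutation of the zones
#' is sampled and every zone is credited with its marginal contribution when
#' appended to the coalition of zones preceding it. The estimator is unbiased
#' for the exact Shapley values, efficiency holds exactly by telescoping, and
#' per-zone standard errors are reported. Distinct coalitions are evaluated
#' once (memoized by bitmask).
#'
#' @inheritParams exact_zone_shap
#' @param N Number of sampled permutations; must be at least twice the zone
#'   count.
#' @param seed Integer seed driving both the permutation draws and any
#'   `"reference_sample"` baseline donor.
#' @return A `zone_attribution` with `values`, per-zone `se`, and the same
#'   base/prediction semantics as [exact_zone_shap()].
#' @export
sampling_zone_shap <- function(model, x, zs, baseline = "reference_mean",
                               reference = NULL, class_index = NULL,
                               N = 5000, seed = 1L) {
  stopifnot(inherits(x, "spectrum"), inherits(zs, "zone_set"))
  nz <- n_zones(zs)
  if (N < 2 * nz) stop("N must be at least twice the zone count (", 2 * nz, ")",
                       call. = FALSE)
  cl <- resolve_class(model, x, class_index)
  background <- baseline_vector(x, baseline, reference, seed)
  memo <- new.env(parent = emptyenv(), size = 4096L)
  n_eval <- 0L
  eval_coalitions <- function(bms) {
    keys <- as.character(bms)
    new <- !vapply(keys, function(k) !is.null(memo[[k]]), logical(1))
    if (any(new)) {
      uniq <- unique(bms[new])
      M <- coalition_matrix(x, zs, background, bitmask_to_masks(uniq, nz))
      p <- predict_proba(model, M)[, cl$class_index]
      for (j in seq_along(uniq)) memo[[as.character(uniq[j])]] <- p[j]
      n_eval <<- n_eval + length(uniq)
    }
    vapply(keys, function(k) memo[[k]], numeric(1), USE.NAMES = FALSE)
  }
  set.seed(seed)
  bits <- 2^(0:(nz - 1))
  contrib <- matrix(0, N, nz)
  for (r in seq_len(N)) {
    ord <- sample.int(nz)
    prefix <- c(0, cumsum(bits[ord]))
    vals <- eval_coalitions(prefix)
    contrib[r, ord] <- diff(vals)
  }
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, stats::sd) / sqrt(N)
  new_attribution(zs, phi,
                  base_value = memo[["0"]],
                  prediction = memo[[as.character(sum(bits))]],
                  class_index = cl$class_index,
                  class_name = model$class_names[cl$class_index],
                  method = "sampling_shap", n_evaluations = n_eval,
                  seed = seed, se = se)
}

#' Explain every spectrum of a dataset
#'
#' Applies one attribution method per row with a shared zone partition and
#' reference, deriving a distinct sub-seed per spectrum from `seed` so the
#' whole run is reproducible yet rows are independently sampled.
#'
#' @param model A [model_adapter()].
#' @param ds A `spectra_set` on the zone grid.
#' @param zs A shared [zone_set()].
#' @param method `"sampling_shap"`, `"exact_shap"` or `"lime"`.
#' @param class_index Class to explain for every row (default: per-row argmax).
#' @param seed Master seed.
#' @param ... Passed to the per-instance explainer
#'   ([sampling_zone_shap()], [exact_zone_shap()] or [zone_lime_explain()]).
#' @return List of `zone_attribution`, one per spectrum.
#' @export
explain_dataset <- function(model, ds, zs, method = c("sampling_shap",
                                                      "exact_shap", "lime"),
                            class_index = NULL, seed = 1L, ...) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "spectra_set"))
  if (length(ds$grid) != length(zs$grid) || any(ds$grid != zs$grid)) {
    stop("dataset grid does not match the zone grid", call. = FALSE)
  }
  lapply(seq_len(n_spectra(ds)), function(i) {
    x <- get_spectrum(ds, i)
    si <- (seed + 7919L * i) %% .Machine$integer.max
    switch(method,
      exact_shap = exact_zone_shap(model, x, zs, class_index = class_index,
                                   seed = si, ...),
      sampling_shap = sampling_zone_shap(model, x, zs,
                                         class_index = class_index,
                                         seed = si, ...),
      lime = zone_lime_explain(model, x, zs, class_index = class_index,
                               seed = si, ...)$attribution)
  })
}

#' Serialize an attribution to a key-value (YAML) document
#'
#' Writes zones (lo, hi), values, base value, prediction, method, seed and the
#' model-call count; LIME attributions add their surrogate block (intercept,
#' fidelity, kernel width, sparsity cap). Numbers carry 6 significant digits.
#'
#' @param a A `zone_attribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attribution <- function(a, path) {
  stopifnot(inherits(a, "zone_attribution"))
  sig <- function(v) as.numeric(signif(v, 6))
  doc <- list(method = a$method, class = a$class_name,
              class_index = a$class_index,
              base_value = sig(a$base_value), prediction = sig(a$prediction),
              n_evaluations = a$n_evaluations, seed = a$seed,
              zones = lapply(seq_along(a$values), function(i) {
                z <- list(lo = a$zone_set$zones$lo[i],
                          hi = a$zone_set$zones$hi[i],
                          value = sig(a$values[i]))
                if (!is.null(a$se)) z$se <- sig(a$se[i])
                z
              }))
  if (!is.null(a$surrogate)) {
    doc$surrogate <- lapply(a$surrogate[c("intercept", "fidelity",
                                          "kernel_width", "K", "n_samples")],
                            function(v) if (is.numeric(v)) sig(v) else v)
    doc$note <- "LIME coefficients are not additive feature attributions; no waterfall path exists"
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}
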