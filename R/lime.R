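#' Proximity weight of a perturbed sample
#'
#' Distance between the instance and a perturbation is the fraction of zones
#' replaced, `d = (# mask zeros) / n`; the kernel is `exp(-d^2 / width^2)`, so
#' the unperturbed instance gets weight 1 and weights decay strictly with the
#' number of replaced zones.
#'
#' @param mask Binary zone mask (1 = retained).
#' @param width Positive kernel width on the replaced-fraction scale.
#' @return Weight in `(0, 1]`.
#' @export
proximity <- function(mask, width = 0.25) {
  if (length(mask) == 0) stop("mask is empty", call. = FALSE)
  if (width <= 0) stop("width must be positive", call. = FALSE)
  d <- mean(mask == 0)
  exp(-d^2 / width^2)
}

weighted_r2 <- function(y, fitted, w) {
  mu <- sum(w * y) / sum(w)
  rss <- sum(w * (y - fitted)^2)
  tss <- sum(w * (y - mu)^2)
  if (tss == 0) return(if (rss <= 1e-12) 1 else -Inf)
  1 - rss / tss
}

## weighted least squares with intercept on selected columns; returns
## list(coef, intercept, fitted) or NULL on rank deficiency
wls_fit <- function(X, y, w, cols) {
  D <- cbind(`(Intercept)` = 1, X[, cols, drop = FALSE])
  fit <- stats::lm.wfit(D, y, w)
  if (fit$rank < ncol(D) || anyNA(fit$coefficients)) return(NULL)
  list(coef = unname(fit$coefficients[-1]),
       intercept = unname(fit$coefficients[1]),
       fitted = drop(D %*% fit$coefficients))
}

#' Zone-based LIME explanation
#'
#' Fits a sparse linear surrogate `g` over binary zone masks in the
#' neighbourhood of `x`: perturbed spectra are generated with
#' [build_perturbation_set()], the model is evaluated on them, and the
#' weighted loss `sum_z pi_x(z) (f(z) - g(mask(z)))^2` is minimised with
#' sparsity enforced by forward selection of at most `K` zones followed by a
#' weighted least-squares refit on the selection. The unperturbed instance
#' (all-ones mask, weight 1) is included in the fit.
#'
#' Unlike Shapley values, the returned coefficients are *not* additive: they
#' do not decompose the path from the expected output to `f(x)`, and
#' [waterfall_data()] refuses them.
#'
#' @inheritParams exact_zone_shap
#' @param spec A [perturbation_spec()]; `spec$n_samples` of at least five times
#'   the zone count is recommended.
#' @param K Sparsity cap: maximum number of zones with nonzero coefficients.
#' @param kernel_width Width of the proximity kernel (replaced-fraction scale).
#' @param seed Overrides `spec$seed` when given, keeping dataset-level runs
#'   reproducible.
#' @param baseline,strategy,n_samples Shortcuts used to build the default
#'   [perturbation_spec()] when `spec` is `NULL`.
#' @return List with `attribution` (a `zone_attribution`, `values` = surrogate
#'   coefficients, `base_value` = surrogate intercept, method `"lime"`) and
#'   `surrogate` (intercept, coefficient vector, fidelity = weighted R^2,
#'   kernel width, `K`, sample count, seed).
#' @export
zone_lime_explain <- function(model, x, zs, spec = NULL, K = 10,
                              kernel_width = 0.25, class_index = NULL,
                              reference = NULL, seed = NULL,
                              baseline = "reference_mean", strategy = NULL,
                              n_samples = NULL) {
  stopifnot(inherits(x, "spectrum"), inherits(zs, "zone_set"))
  nz <- n_zones(zs)
  if (is.null(spec)) {
    if (is.null(strategy)) {
      strategy <- if (is.null(reference)) "input_augmented"
                  else "dataset_substitution"
    }
    spec <- perturbation_spec(strategy = strategy, baseline = baseline,
                              n_samples = if (is.null(n_samples))
                                max(200L, 5L * nz) else n_samples,
                              seed = if (is.null(seed)) 1L else seed)
  }
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  cl <- resolve_class(model, x, class_index)
  ps <- build_perturbation_set(x, zs, spec, reference)
  X <- rbind(ps$masks, rep(1L, nz))
  Y <- rbind(ps$samples, matrix(x$intensities, nrow = 1))
  y <- predict_proba(model, Y)[, cl$class_index]
  w <- apply(X, 1, proximity, width = kernel_width)
  K <- min(K, nz)
  selected <- integer(0)
  for (step in seq_len(K)) {
    candidates <- setdiff(seq_len(nz), selected)
    rss <- vapply(candidates, function(j) {
      f <- wls_fit(X, y, w, c(selected, j))
      if (is.null(f)) Inf else sum(w * (y - f$fitted)^2)
    }, numeric(1))
    if (all(!is.finite(rss))) break
    selected <- c(selected, candidates[which.min(rss)])
  }
  fit <- wls_fit(X, y, w, selected)
  if (is.null(fit)) {
    stop("surrogate design is rank-deficient after selection; ",
         "increase spec$n_samples", call. = FALSE)
  }
  values <- numeric(nz)
  values[selected] <- fit$coef
  fidelity <- weighted_r2(y, fit$fitted, w)
  surrogate <- list(intercept = fit$intercept, coefficients = values,
                    fidelity = fidelity, kernel_width = kernel_width,
                    K = K, n_samples = spec$n_samples, seed = spec$seed)
  att <- new_attribution(zs, values, base_value = fit$intercept,
                         prediction = cl$fx, class_index = cl$class_index,
                         class_name = model$class_names[cl$class_index],
                         method = "lime",
                         n_evaluations = nrow(Y), seed = spec$seed,
                         surrogate = surrogate)
  list(attribution = att, surrogate = surrogate)
}
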