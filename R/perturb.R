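#' Specify how perturbed spectra are generated
#'
#' Three strategies cover decreasing data availability:
#' `dataset_substitution` copies each replaced zone from a reference spectrum
#' drawn uniformly per sample; `transform_augmented` copies it from a reference
#' spectrum after a random smoothing/sharpening transform, widening the
#' variation beyond what the reference holds; `input_augmented` needs no
#' reference at all and replaces each masked zone by a transform of the
#' instance's own zone.
#'
#' @param strategy One of `"dataset_substitution"`, `"transform_augmented"`,
#'   `"input_augmented"`.
#' @param baseline Replacement values used by the Shapley explainers:
#'   `"reference_mean"` (pointwise mean of the reference set — the "expected
#'   mean value" replacement), `"zero"`, or `"reference_sample"` (one reference
#'   spectrum drawn with `seed`).
#' @param n_samples Number of perturbed spectra to generate.
#' @param seed Integer seed; mandatory, every strategy draws random masks.
#' @param transform_params List with `smooth_width` (odd points) and
#'   `sharpen_strength` (unsharp-mask multiplier) for the transform strategies.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(strategy = c("dataset_substitution",
                                           "transform_augmented",
                                           "input_augmented"),
                              baseline = c("reference_mean", "zero",
                                           "reference_sample"),
                              n_samples = 100, seed = NULL,
                              transform_params = list(smooth_width = 5,
                                                      sharpen_strength = 1)) {
  strategy <- match.arg(strategy)
  baseline <- match.arg(baseline)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (is.null(seed)) stop("seed is mandatory: mask draws are stochastic",
                          call. = FALSE)
  structure(list(strategy = strategy, baseline = baseline,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 transform_params = transform_params),
            class = "perturbation_spec")
}

## Full-length replacement vector realising one baseline choice.
baseline_vector <- function(x, baseline, reference = NULL, seed = NULL) {
  switch(baseline,
    zero = numeric(length(x$grid)),
    reference_mean = {
      if (is.null(reference)) stop("baseline 'reference_mean' needs a reference set",
                                   call. = FALSE)
      check_reference_grid(x, reference)
      colMeans(reference$intensities)
    },
    reference_sample = {
      if (is.null(reference)) stop("baseline 'reference_sample' needs a reference set",
                                   call. = FALSE)
      if (is.null(seed)) stop("baseline 'reference_sample' needs a seed",
                              call. = FALSE)
      check_reference_grid(x, reference)
      set.seed(seed)
      reference$intensities[sample.int(n_spectra(reference), 1), ]
    },
    stop("unknown baseline '", baseline, "'", call. = FALSE))
}

check_reference_grid <- function(x, reference) {
  if (length(reference$grid) != length(x$grid) ||
      any(reference$grid != x$grid)) {
    stop("reference set is on a different wavenumber grid than the instance; ",
         "resample explicitly first", call. = FALSE)
  }
  invisible(TRUE)
}

#' Replace the masked-out zones of a spectrum
#'
#' Zones with mask 1 are kept bit-exactly from `x`; zones with mask 0 are
#' overwritten with the chosen baseline values restricted to the zone.
#'
#' @param x A [spectrum()].
#' @param zs A [zone_set()] on `x`'s grid.
#' @param mask Binary vector, one entry per zone (1 = retain).
#' @param baseline `"reference_mean"`, `"zero"` or `"reference_sample"`.
#' @param reference `spectra_set` required by the reference baselines.
#' @param seed Seed for `"reference_sample"` donor choice.
#' @return Numeric intensity vector of the perturbed spectrum.
#' @export
replace_zones <- function(x, zs, mask, baseline = "reference_mean",
                          reference = NULL, seed = NULL) {
  stopifnot(inherits(x, "spectrum"), inherits(zs, "zone_set"))
  if (length(mask) != n_zones(zs)) {
    stop("mask length ", length(mask), " != zone count ", n_zones(zs),
         call. = FALSE)
  }
  bg <- baseline_vector(x, baseline, reference, seed)
  out <- x$intensities
  for (i in which(mask == 0)) {
    idx <- zone_indices(zs, i)
    out[idx] <- bg[idx]
  }
  out
}

#' Smooth or sharpen one zone of a spectrum
#'
#' `smooth` applies a centered moving average of width `strength` (odd points)
#' inside the zone; `sharpen` applies unsharp masking,
#' `x + strength * (x - smoothed x)`, with the smoothing width taken from
#' `smooth_width`. Points outside the zone are untouched.
#'
#' @param x A [spectrum()].
#' @param zs A [zone_set()].
#' @param zone Zone number to transform.
#' @param kind `"smooth"` or `"sharpen"`.
#' @param strength Positive scalar: the window width for `smooth`, the
#'   residual multiplier for `sharpen`.
#' @param smooth_width Odd window used by `sharpen`'s internal smoothing.
#' @return Numeric intensity vector.
#' @export
transform_zone <- function(x, zs, zone, kind = c("smooth", "sharpen"),
                           strength = 5, smooth_width = 5) {
  kind <- match.arg(kind)
  stopifnot(inherits(x, "spectrum"), inherits(zs, "zone_set"), strength > 0)
  idx <- zone_indices(zs, zone)
  w <- if (kind == "smooth") as.integer(strength) else as.integer(smooth_width)
  if (w %% 2 == 0) w <- w + 1L
  if (length(idx) < w) {
    stop("zone ", zone, " spans ", length(idx),
         " points, narrower than the smoothing width ", w, call. = FALSE)
  }
  out <- x$intensities
  seg <- out[idx]
  sm <- smooth_ma(seg, w)
  out[idx] <- if (kind == "smooth") sm else seg + strength * (seg - sm)
  out
}

## Random binary mask over zones: uniform over {0,1}^n minus the all-ones
## vector (keeping all zones tells the explainer nothing).
draw_mask <- function(n) {
  repeat {
    m <- sample(c(0L, 1L), n, replace = TRUE)
    if (any(m == 0L)) return(m)
  }
}

#' Build the perturbation set Z for one instance
#'
#' Draws `spec$n_samples` random zone masks (uniform over non-trivial binary
#' vectors: all-ones excluded, all-zeros included as the baseline anchor) and
#' fills each masked-out zone according to the strategy in `spec`. Every
#' retained zone equals the original spectrum bit-exactly.
#'
#' @param x A [spectrum()].
#' @param zs A [zone_set()] on `x`'s grid.
#' @param spec A [perturbation_spec()].
#' @param reference `spectra_set` (required unless `strategy` is
#'   `"input_augmented"`).
#' @return Object of class `perturbation_set`: list with `samples`
#'   (`n_samples x n_points` matrix), `masks` (`n_samples x n_zones` binary
#'   matrix) and `spec`.
#' @export
build_perturbation_set <- function(x, zs, spec, reference = NULL) {
  stopifnot(inherits(spec, "perturbation_spec"))
  nz <- n_zones(zs)
  needs_ref <- spec$strategy %in% c("dataset_substitution", "transform_augmented")
  if (needs_ref) {
    if (is.null(reference)) stop("strategy '", spec$strategy,
                                 "' requires a reference set", call. = FALSE)
    check_reference_grid(x, reference)
  }
  set.seed(spec$seed)
  masks <- t(matrix(vapply(seq_len(spec$n_samples), function(k) draw_mask(nz),
                           integer(nz)), nrow = nz))
  tp <- spec$transform_params
  samples <- matrix(0, spec$n_samples, length(x$grid))
  for (k in seq_len(spec$n_samples)) {
    out <- x$intensities
    replaced <- which(masks[k, ] == 0L)
    if (length(replaced)) {
      donor_vec <- switch(spec$strategy,
        dataset_substitution =
          reference$intensities[sample.int(n_spectra(reference), 1), ],
        transform_augmented = {
          d <- get_spectrum(reference, sample.int(n_spectra(reference), 1))
          kind <- sample(c("smooth", "sharpen"), 1)
          v <- d$intensities
          for (i in replaced) {
            v <- transform_whole(v, zone_indices(zs, i), kind, tp)
          }
          v
        },
        input_augmented = {
          kind <- sample(c("smooth", "sharpen"), 1)
          v <- x$intensities
          for (i in replaced) {
            v <- transform_whole(v, zone_indices(zs, i), kind, tp)
          }
          v
        })
      for (i in replaced) {
        idx <- zone_indices(zs, i)
        out[idx] <- donor_vec[idx]
      }
    }
    samples[k, ] <- out
  }
  structure(list(samples = samples, masks = masks, spec = spec,
                 grid = x$grid, instance = x$intensities),
            class = "perturbation_set")
}

## In-place zone transform on a bare vector; falls back to leaving a zone
## untouched when it is narrower than the smoothing window (a transform must
## never fail mid-sampling on a legitimate narrow zone).
transform_whole <- function(v, idx, kind, tp) {
  w <- as.integer(tp$smooth_width)
  if (w %% 2 == 0) w <- w + 1L
  if (length(idx) < w) return(v)
  seg <- v[idx]
  sm <- smooth_ma(seg, w)
  v[idx] <- if (kind == "smooth") sm else seg + tp$sharpen_strength * (seg - sm)
  v
}

#' Export a perturbation set as a spectra file
#'
#' @param ps A `perturbation_set`.
#' @param path Output path (wide-format delimited text).
#' @return `path`, invisibly.
#' @export
write_perturbation_set <- function(ps, path) {
  ds <- spectra_set(ps$grid, ps$samples,
                    ids = sprintf("perturb_%03d", seq_len(nrow(ps$samples))))
  write_spectra(ds, path)
}
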