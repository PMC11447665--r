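#' @importFrom tibble tibble
NULL

## Centered moving average whose half-window shrinks symmetrically near the
## edges: exact on straight-line segments everywhere, including the ends.
## Sums are taken locally (stats::filter), not via a global cumulative sum,
## so near-zero stretches between strong bands keep full relative precision.
smooth_ma <- function(y, window) {
  window <- as.integer(window)
  stopifnot(window >= 1, window %% 2 == 1)
  n <- length(y)
  if (window == 1 || n < 3) return(y)
  h <- (window - 1) %/% 2
  out <- as.numeric(stats::filter(y, rep(1 / window, window), sides = 2))
  for (i in c(seq_len(min(h, n)), seq(max(n - h + 1, 1), n))) {
    hi <- min(h, i - 1L, n - i)
    out[i] <- mean(y[(i - hi):(i + hi)])
  }
  out
}

## scipy-style topographic prominence: height above the higher of the two
## minima separating the peak from the nearest higher ground on each side.
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- if (p > 1) y[seq_len(p - 1)] else numeric(0)
    right <- if (p < length(y)) y[seq(p + 1, length(y))] else numeric(0)
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(left[seq(max(higher_l) + 1, length(left))])
              else min(c(left, h))
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)])
              else min(c(right, h))
    h - max(base_l, base_r)
  }, numeric(1))
}

#' Detect peaks and the valleys between them
#'
#' Peaks are local maxima of the smoothed spectrum whose topographic prominence
#' exceeds `min_prominence` times the intensity range; valleys are the minima
#' of the smoothed spectrum between consecutive retained peaks. This realises
#' the derivative criterion for extrema (first derivative zero, second
#' derivative sign giving the type) robustly on sampled, noisy data.
#'
#' @param s A [spectrum()].
#' @param smooth_window Odd window (points) of the centered moving average
#'   applied before differencing; 1 disables smoothing.
#' @param min_prominence Prominence threshold as a fraction of the spectrum's
#'   intensity range, in `[0, 1)`.
#' @return List with numeric vectors `peaks` and `valleys` (cm^-1, positions on
#'   the original grid) and their index counterparts `peak_idx`, `valley_idx`.
#' @export
detect_extrema <- function(s, smooth_window = 5, min_prominence = 0.01) {
  stopifnot(inherits(s, "spectrum"))
  if (smooth_window < 1 || smooth_window %% 2 != 1) {
    stop("smooth_window must be an odd count >= 1", call. = FALSE)
  }
  if (min_prominence < 0 || min_prominence >= 1) {
    stop("min_prominence must lie in [0, 1)", call. = FALSE)
  }
  n <- length(s$grid)
  if (n < smooth_window) {
    stop("spectrum has ", n, " points, fewer than smooth_window = ",
         smooth_window, call. = FALSE)
  }
  y <- smooth_ma(s$intensities, smooth_window)
  d <- diff(y)
  ## interior strict sign changes; the >=/< pair resolves flat tops leftwards
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(cand)) {
    prom <- peak_prominences(y, cand)
    rng <- diff(range(s$intensities))
    keep <- prom >= min_prominence * rng & prom > 0
    cand <- cand[keep]
  }
  valley_idx <- integer(0)
  if (length(cand) >= 2) {
    valley_idx <- vapply(seq_len(length(cand) - 1), function(k) {
      span <- seq(cand[k] + 1L, cand[k + 1] - 1L)
      span[which.min(y[span])]
    }, integer(1))
  }
  list(peaks = s$grid[cand], valleys = s$grid[valley_idx],
       peak_idx = cand, valley_idx = valley_idx)
}

#' Build a zone set
#'
#' @param starts,ends 1-based inclusive index ranges on `grid`; zone `k` covers
#'   `grid[starts[k]]` to `grid[ends[k]]`, zones are contiguous
#'   (`starts[k+1] == ends[k] + 1`) and jointly cover the axis.
#' @param grid The wavenumber axis the zones partition.
#' @param provenance One of `"local"`, `"global"`, `"user"`.
#' @param params Optional list of the detection parameters that produced it.
#' @return Object of class `zone_set`; `$zones` is a tibble with columns
#'   `zone`, `lo`, `hi`, `start`, `end`.
#' @export
zone_set <- function(starts, ends, grid, provenance = "user", params = list()) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  n <- length(grid)
  stopifnot(length(starts) == length(ends), length(starts) >= 1)
  if (starts[1] != 1L || ends[length(ends)] != n) {
    stop("zones must cover the full grid", call. = FALSE)
  }
  if (any(starts > ends)) stop("each zone needs start <= end", call. = FALSE)
  if (length(starts) > 1 && any(starts[-1] != ends[-length(ends)] + 1L)) {
    stop("zones must be contiguous and non-overlapping", call. = FALSE)
  }
  z <- tibble::tibble(zone = seq_along(starts), lo = grid[starts],
                      hi = grid[ends], start = starts, end = ends)
  structure(list(zones = z, grid = as.numeric(grid),
                 provenance = match.arg(provenance, c("local", "global", "user")),
                 params = params),
            class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d zones (%s) on %d points, %g-%g cm^-1\n",
              n_zones(x), x$provenance, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Number of zones
#' @param zs A `zone_set`.
#' @return Integer zone count.
#' @export
n_zones <- function(zs) nrow(zs$zones)

#' Grid-point indices of one zone
#' @param zs A `zone_set`.
#' @param i Zone number.
#' @return Integer vector of grid indices covered by zone `i`.
#' @export
zone_indices <- function(zs, i) seq(zs$zones$start[i], zs$zones$end[i])

#' Per-zone mean intensities
#' @param zs A `zone_set`.
#' @param X Intensity matrix on `zs$grid` (or a single vector).
#' @return Matrix `n_rows x n_zones` of zone means.
#' @export
zone_means <- function(zs, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == length(zs$grid))
  out <- vapply(seq_len(n_zones(zs)),
                function(i) rowMeans(X[, zone_indices(zs, i), drop = FALSE]),
                numeric(nrow(X)))
  matrix(out, nrow = nrow(X))
}

#' Partition the axis at valley positions
#'
#' `k` valleys give `k + 1` zones; each valley's grid point starts the zone to
#' its right. Zones narrower than `min_zone_width` grid points are merged into
#' the neighbouring zone whose shared boundary has the lower intensity, so no
#' degenerate single-point coalition survives.
#'
#' @param s The [spectrum()] being segmented (supplies grid and the boundary
#'   intensities used when merging narrow zones).
#' @param valleys Valley positions in cm^-1, sorted, strictly inside the grid
#'   range, no duplicates.
#' @param min_zone_width Minimum zone width in grid points (default 3).
#' @param provenance Provenance tag for the resulting zone set.
#' @return A [zone_set()] with `length(valleys) + 1` zones before merging.
#' @export
zones_from_valleys <- function(s, valleys, min_zone_width = 3,
                               provenance = "local") {
  stopifnot(inherits(s, "spectrum"))
  n <- length(s$grid)
  valleys <- as.numeric(valleys)
  if (length(valleys) == 0) {
    return(zone_set(1L, n, s$grid, provenance = provenance))
  }
  if (is.unsorted(valleys, strictly = FALSE)) stop("valleys must be sorted",
                                                   call. = FALSE)
  idx <- vapply(valleys, function(v) which.min(abs(s$grid - v)), integer(1))
  if (anyDuplicated(idx)) {
    stop("duplicate valley positions after snapping to the grid: ",
         paste(unique(s$grid[idx[duplicated(idx)]]), collapse = ", "),
         call. = FALSE)
  }
  if (any(idx <= 1L | idx >= n)) {
    stop("valleys must lie strictly inside the grid range", call. = FALSE)
  }
  starts <- c(1L, idx)
  ends <- c(idx - 1L, n)
  zs <- zone_set(starts, ends, s$grid, provenance = provenance)
  merge_narrow_zones(zs, s$intensities, min_zone_width)
}

merge_narrow_zones <- function(zs, y, min_zone_width) {
  starts <- zs$zones$start; ends <- zs$zones$end
  repeat {
    w <- ends - starts + 1L
    narrow <- which(w < min_zone_width)
    if (!length(narrow) || length(starts) == 1L) break
    j <- narrow[1]
    if (j == 1L) drop_right <- TRUE
    else if (j == length(starts)) drop_right <- FALSE
    else {
      ## boundary intensity with each neighbour: the zone's own first point
      ## (valley starting it) vs. the first point of the zone to its right
      drop_right <- y[starts[j + 1]] < y[starts[j]]
    }
    if (drop_right) { # absorb into right neighbour
      starts <- starts[-(j + 1)]; ends <- ends[-j]
    } else {          # absorb into left neighbour
      starts <- starts[-j]; ends <- ends[-(j - 1)]
    }
  }
  zone_set(starts, ends, zs$grid, provenance = zs$provenance, params = zs$params)
}

#' Zones of a single spectrum (local explanation support)
#'
#' Runs [detect_extrema()] and [zones_from_valleys()] on one spectrum.
#'
#' @inheritParams detect_extrema
#' @inheritParams zones_from_valleys
#' @return A [zone_set()] with provenance `"local"`.
#' @export
local_zones <- function(s, smooth_window = 5, min_prominence = 0.01,
                        min_zone_width = 3) {
  ex <- detect_extrema(s, smooth_window, min_prominence)
  zs <- zones_from_valleys(s, ex$valleys, min_zone_width, provenance = "local")
  zs$params <- list(smooth_window = smooth_window,
                    min_prominence = min_prominence,
                    min_zone_width = min_zone_width)
  zs
}

#' Zones of a whole dataset (global explanation support)
#'
#' Segments the pointwise mean spectrum of the dataset, so one zone partition
#' is shared by every spectrum.
#'
#' @param ds A non-empty `spectra_set`.
#' @inheritParams local_zones
#' @return A [zone_set()] with provenance `"global"`.
#' @export
global_zones <- function(ds, smooth_window = 5, min_prominence = 0.01,
                         min_zone_width = 3) {
  stopifnot(inherits(ds, "spectra_set"))
  if (n_spectra(ds) == 0) stop("dataset is empty", call. = FALSE)
  m <- spectrum(ds$grid, colMeans(ds$intensities), id = "mean")
  zs <- local_zones(m, smooth_window, min_prominence, min_zone_width)
  zs$provenance <- "global"
  zs
}

#' Load user-defined zones from a delimited file
#'
#' The file has header columns `lo,hi` (cm^-1). Bounds are snapped to the
#' nearest grid points; gaps between declared zones (and before the first /
#' after the last) are auto-filled with background zones so that the partition
#' covers the whole axis.
#'
#' @param path Zone file (comment lines starting with `#` are ignored).
#' @param grid The wavenumber axis to snap onto.
#' @return A [zone_set()] with provenance `"user"`.
#' @export
load_user_zones <- function(path, grid) {
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("lo", "hi") %in% names(tab))) {
    stop("zone file must have columns lo, hi", call. = FALSE)
  }
  n <- length(grid)
  snap <- function(v) vapply(v, function(x) which.min(abs(grid - x)), integer(1))
  starts <- snap(tab$lo); ends <- snap(tab$hi)
  if (any(starts > ends)) stop("zone with lo > hi in ", path, call. = FALSE)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (length(starts) > 1) {
    ov <- which(starts[-1] <= ends[-length(ends)])
    if (length(ov)) {
      stop("overlapping zones: [", grid[starts[ov[1] + 1]], ", ",
           grid[ends[ov[1] + 1]], "] overlaps [", grid[starts[ov[1]]], ", ",
           grid[ends[ov[1]]], "]", call. = FALSE)
    }
  }
  ## fill gaps with background zones
  fs <- integer(0); fe <- integer(0)
  cursor <- 1L
  for (k in seq_along(starts)) {
    if (starts[k] > cursor) { fs <- c(fs, cursor); fe <- c(fe, starts[k] - 1L) }
    fs <- c(fs, starts[k]); fe <- c(fe, ends[k])
    cursor <- ends[k] + 1L
  }
  if (cursor <= n) { fs <- c(fs, cursor); fe <- c(fe, n) }
  zone_set(fs, fe, grid, provenance = "user")
}

#' Write a zone set to a delimited file
#'
#' Provenance and detection parameters are stored as `#` comment lines above a
#' `lo,hi` table, so the file reloads with [load_user_zones()].
#'
#' @param zs A `zone_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zones <- function(zs, path) {
  stopifnot(inherits(zs, "zone_set"))
  meta <- c(paste0("# provenance: ", zs$provenance),
            if (length(zs$params)) {
              paste0("# ", names(zs$params), ": ", unlist(zs$params))
            })
  lines <- c(meta, "lo,hi",
             sprintf("%.17g,%.17g", zs$zones$lo, zs$zones$hi))
  writeLines(lines, path)
  invisible(path)
}
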