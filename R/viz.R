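zone_label <- function(lo, hi) sprintf("%g-%g cm^-1", lo, hi)

## |value| descending, ties broken by ascending zone lo: deterministic plots
rank_zones <- function(values, lo) order(-abs(values), lo)

#' Waterfall data: the additive path from base value to prediction
#'
#' Orders zones by absolute contribution, keeps the `top_k` largest and sums
#' the rest into a remainder row, preserving the additive identity
#' `sum(rows) + remainder = prediction - base_value`. Refused for LIME
#' attributions, whose coefficients are not additive.
#'
#' @param a A SHAP `zone_attribution` (`exact_shap` or `sampling_shap`).
#' @param top_k Number of individually shown zones.
#' @return Object of class `waterfall_data`: tibble `rows` (label, lo, hi,
#'   contribution), `remainder`, `n_remainder`, `base_value`, `prediction`.
#' @export
waterfall_data <- function(a, top_k = 9) {
  stopifnot(inherits(a, "zone_attribution"))
  if (a$method == "lime") {
    stop("waterfall plots require additive attributions; LIME surrogate ",
         "coefficients do not sum along the path from the expected to the ",
         "predicted output", call. = FALSE)
  }
  ord <- rank_zones(a$values, a$zone_set$zones$lo)
  shown <- ord[seq_len(min(top_k, length(ord)))]
  rest <- setdiff(ord, shown)
  rows <- tibble::tibble(label = zone_label(a$zone_set$zones$lo[shown],
                                            a$zone_set$zones$hi[shown]),
                         lo = a$zone_set$zones$lo[shown],
                         hi = a$zone_set$zones$hi[shown],
                         contribution = a$values[shown])
  structure(list(rows = rows, remainder = sum(a$values[rest]),
                 n_remainder = length(rest), base_value = a$base_value,
                 prediction = a$prediction),
            class = "waterfall_data")
}

#' Saliency map: per-wavenumber signed relevance
#'
#' Spreads each zone's attribution over its grid points, normalised by the
#' largest absolute attribution so the map lives in `[-1, 1]` and is
#' piecewise constant with breakpoints exactly at zone boundaries. An
#' all-zero attribution maps to an all-zero saliency (no division).
#'
#' @param a A `zone_attribution` (any method).
#' @return Tibble with columns `wavenumber`, `relevance`, `zone`.
#' @export
saliency_data <- function(a) {
  stopifnot(inherits(a, "zone_attribution"))
  top <- max(abs(a$values))
  scaled <- if (top == 0) a$values else a$values / top
  zone_of <- rep(seq_along(a$values),
                 a$zone_set$zones$end - a$zone_set$zones$start + 1L)
  tibble::tibble(wavenumber = a$zone_set$grid,
                 relevance = scaled[zone_of], zone = zone_of)
}

#' Beeswarm summary data across a dataset
#'
#' One point per (spectrum, zone): the zone's attribution value, coloured by
#' the spectrum's zone mean intensity min-max normalised per zone across the
#' dataset (a constant zone maps to 0). Zones are ordered by descending mean
#' absolute attribution, ties by ascending zone start.
#'
#' @param atts List of `zone_attribution` sharing one zone set.
#' @param ds The `spectra_set` the attributions were computed on, row-aligned
#'   with `atts`.
#' @return Object of class `summary_data`: long tibble `points`
#'   (zone, label, rank, spectrum, value, color) plus `zone_order` and
#'   `mean_abs`.
#' @export
summary_data <- function(atts, ds) {
  stopifnot(length(atts) >= 1, inherits(ds, "spectra_set"),
            length(atts) == n_spectra(ds))
  zs <- atts[[1]]$zone_set
  same <- vapply(atts, function(a) {
    identical(a$zone_set$zones$start, zs$zones$start) &&
      identical(a$zone_set$zones$end, zs$zones$end)
  }, logical(1))
  if (!all(same)) stop("attributions use mixed zone sets", call. = FALSE)
  V <- t(matrix(vapply(atts, function(a) a$values, numeric(n_zones(zs))),
                nrow = n_zones(zs)))
  M <- zone_means(zs, ds$intensities)
  color <- apply(M, 2, function(col) {
    rng <- max(col) - min(col)
    if (rng == 0) rep(0, length(col)) else (col - min(col)) / rng
  })
  color <- matrix(color, nrow = nrow(M))
  mean_abs <- colMeans(abs(V))
  ord <- rank_zones(mean_abs, zs$zones$lo)
  rank <- match(seq_len(n_zones(zs)), ord)
  points <- tibble::tibble(
    zone = rep(seq_len(n_zones(zs)), each = nrow(V)),
    label = rep(zone_label(zs$zones$lo, zs$zones$hi), each = nrow(V)),
    rank = rep(rank, each = nrow(V)),
    spectrum = rep(ds$ids, times = n_zones(zs)),
    value = as.vector(V),
    color = as.vector(color))
  structure(list(points = points, zone_order = ord, mean_abs = mean_abs,
                 zone_set = zs),
            class = "summary_data")
}

#' Waterfall plot
#' @param wd A [waterfall_data()] object.
#' @return A ggplot: red bars push the prediction up, blue bars pull it down,
#'   from `E[f(x)]` at the bottom to `f(x)` at the top.
#' @export
plot_waterfall <- function(wd) {
  stopifnot(inherits(wd, "waterfall_data"))
  labs <- c(wd$rows$label,
            sprintf("%d remaining zones", wd$n_remainder))
  contr <- c(wd$rows$contribution, wd$remainder)
  start <- wd$base_value + cumsum(c(0, contr[-length(contr)]))
  df <- data.frame(label = factor(labs, levels = rev(labs)),
                   from = start, to = start + contr,
                   sign = ifelse(contr >= 0, "positive", "negative"))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = from, xend = to, y = label,
                                       yend = label, colour = sign),
                          linewidth = 4, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = wd$base_value, linetype = 2) +
    ggplot2::geom_vline(xintercept = wd$prediction, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(positive = "#d62728",
                                            negative = "#1f77b4")) +
    ggplot2::labs(x = sprintf("model output  (E[f(x)] = %.3f,  f(x) = %.3f)",
                              wd$base_value, wd$prediction),
                  y = NULL, title = "Zone contributions") +
    ggplot2::theme_minimal()
}

#' Relevance-coefficient plot: one signed bar per zone
#' @param a A `zone_attribution`.
#' @return A ggplot of zone attributions over the wavenumber axis.
#' @export
plot_relevance <- function(a) {
  stopifnot(inherits(a, "zone_attribution"))
  z <- a$zone_set$zones
  df <- data.frame(lo = z$lo, hi = z$hi, value = a$values,
                   sign = ifelse(a$values >= 0, "positive", "negative"))
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = lo, xmax = hi, ymin = pmin(value, 0),
                                    ymax = pmax(value, 0), fill = sign),
                       show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(positive = "#d62728",
                                          negative = "#1f77b4")) +
    ggplot2::labs(x = "wavenumber (cm^-1)",
                  y = sprintf("%s value", a$method),
                  title = sprintf("Zone relevance, class '%s'", a$class_name)) +
    ggplot2::theme_minimal()
}

#' Saliency-map plot over a spectrum
#' @param a A `zone_attribution`.
#' @param s Optional [spectrum()] drawn behind the map (scaled to `[0, 1]`).
#' @return A ggplot of normalised relevance versus wavenumber.
#' @export
plot_saliency <- function(a, s = NULL) {
  sd <- saliency_data(a)
  p <- ggplot2::ggplot(sd, ggplot2::aes(x = wavenumber)) +
    ggplot2::geom_line(ggplot2::aes(y = relevance), colour = "#d62728") +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = "wavenumber (cm^-1)", y = "normalised relevance",
                  title = sprintf("Saliency map (%s), class '%s'",
                                  a$method, a$class_name)) +
    ggplot2::theme_minimal()
  if (!is.null(s)) {
    rng <- range(s$intensities)
    sc <- if (diff(rng) == 0) s$intensities * 0 else
      (s$intensities - rng[1]) / diff(rng)
    p <- p + ggplot2::geom_line(data = data.frame(wavenumber = s$grid, y = sc),
                                ggplot2::aes(y = y), colour = "grey60")
  }
  p
}

#' Beeswarm summary plot
#' @param smd A [summary_data()] object.
#' @param top_k Number of zones shown (most important first).
#' @return A ggplot: attribution value on the horizontal axis, zones in
#'   descending importance, points coloured blue (low zone intensity) to pink
#'   (high zone intensity).
#' @export
plot_summary <- function(smd, top_k = 15) {
  stopifnot(inherits(smd, "summary_data"))
  pts <- smd$points[smd$points$rank <= top_k, ]
  lev <- unique(pts$label[order(pts$rank, decreasing = TRUE)])
  pts$label <- factor(pts$label, levels = lev)
  ggplot2::ggplot(pts, ggplot2::aes(x = value, y = label, colour = color)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 1, alpha = 0.8) +
    ggplot2::scale_colour_gradient(low = "#1f77b4", high = "#e377c2",
                                   name = "zone intensity") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "attribution value", y = NULL,
                  title = "Zone importance summary") +
    ggplot2::theme_minimal()
}

#' Zone-boundary overlay plot
#' @param s A [spectrum()].
#' @param zs A [zone_set()] on the same grid.
#' @param extrema Optional result of [detect_extrema()]; peaks drawn red,
#'   valleys green.
#' @return A ggplot of the spectrum with zone boundaries.
#' @export
plot_zones <- function(s, zs, extrema = NULL) {
  stopifnot(inherits(s, "spectrum"), inherits(zs, "zone_set"))
  df <- data.frame(wavenumber = s$grid, intensity = s$intensities)
  p <- ggplot2::ggplot(df, ggplot2::aes(wavenumber, intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = zs$zones$lo[-1], colour = "grey50",
                        linetype = 2) +
    ggplot2::labs(x = "wavenumber (cm^-1)", y = "intensity (a.u.)",
                  title = sprintf("%d spectral zones (%s)", n_zones(zs),
                                  zs$provenance)) +
    ggplot2::theme_minimal()
  if (!is.null(extrema)) {
    p <- p +
      ggplot2::geom_vline(xintercept = extrema$peaks, colour = "#d62728",
                          alpha = 0.6) +
      ggplot2::geom_vline(xintercept = extrema$valleys, colour = "#2ca02c",
                          alpha = 0.6)
  }
  p
}

#' Write a plot to disk
#' @param p A ggplot object.
#' @param path Output file path.
#' @param format `"png"`, `"svg"` or `"pdf"`.
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
render <- function(p, path, format = c("png", "svg", "pdf"),
                   width = 7, height = 5) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown format '", format[1],
                                              "'; use png, svg or pdf",
                                              call. = FALSE))
  dev <- switch(format,
                png = function(f, ...) grDevices::png(f, ..., units = "in",
                                                      res = 150),
                svg = grDevices::svg,
                pdf = grDevices::pdf)
  dev(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Export plot data as delimited text (for headless inspection)
#' @param obj A `waterfall_data`, `summary_data` or saliency tibble.
#' @param path Output path (tab-separated, 6 significant digits).
#' @return `path`, invisibly.
#' @export
write_plot_data <- function(obj, path) {
  df <- if (inherits(obj, "waterfall_data")) {
    rbind(data.frame(label = obj$rows$label,
                     contribution = obj$rows$contribution),
          data.frame(label = sprintf("%d remaining zones", obj$n_remainder),
                     contribution = obj$remainder))
  } else if (inherits(obj, "summary_data")) {
    as.data.frame(obj$points)
  } else {
    as.data.frame(obj)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
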