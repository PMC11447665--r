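#' Construct a single spectrum
#'
#' A spectrum is a strictly ascending wavenumber grid (cm^-1) paired with one
#' intensity value per grid point (arbitrary units).
#'
#' @param grid Numeric vector of wavenumbers in cm^-1, strictly increasing.
#' @param intensities Numeric vector of intensities, same length as `grid`.
#' @param id Character label for the spectrum.
#' @return An object of class `spectrum` with fields `grid`, `intensities`, `id`.
#' @export
#' @examples
#' s <- spectrum(seq(400, 1800, by = 2), dnorm(seq(400, 1800, by = 2), 1000, 20))
spectrum <- function(grid, intensities, id = "spectrum") {
  grid <- as.numeric(grid)
  intensities <- as.numeric(intensities)
  if (length(grid) != length(intensities)) {
    stop("`grid` and `intensities` must have equal length (", length(grid),
         " vs ", length(intensities), ")", call. = FALSE)
  }
  if (anyNA(grid) || anyNA(intensities)) {
    stop("spectrum must not contain missing values", call. = FALSE)
  }
  check_ascending(grid)
  structure(list(grid = grid, intensities = intensities, id = as.character(id)[1]),
            class = "spectrum")
}

check_ascending <- function(grid) {
  bad <- which(diff(grid) <= 0)
  if (length(bad)) {
    stop("grid not ascending: wavenumber at position ", bad[1] + 1,
         " (", grid[bad[1] + 1], ") does not exceed its predecessor (",
         grid[bad[1]], ")", call. = FALSE)
  }
  invisible(grid)
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s'> %d points, %g-%g cm^-1\n",
              x$id, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Construct a set of spectra sharing one wavenumber grid
#'
#' @param grid Shared wavenumber axis (cm^-1), strictly increasing.
#' @param intensities Numeric matrix, one row per spectrum, `length(grid)` columns.
#' @param ids Character row identifiers (default `spec_1`, ...).
#' @param labels Optional class label per row (`NA` allowed for unlabeled data).
#' @param batches Optional batch/bottle identifier per row.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(grid, intensities, ids = NULL, labels = NULL,
                        batches = NULL) {
  grid <- as.numeric(grid)
  check_ascending(grid)
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(grid)) {
    stop("intensity matrix has ", ncol(intensities),
         " columns but the grid has ", length(grid), " points", call. = FALSE)
  }
  if (anyNA(intensities)) stop("intensities must not contain missing values",
                               call. = FALSE)
  n <- nrow(intensities)
  if (is.null(ids)) ids <- sprintf("spec_%d", seq_len(n))
  if (is.null(labels)) labels <- rep(NA_character_, n)
  if (is.null(batches)) batches <- rep(NA_character_, n)
  stopifnot(length(ids) == n, length(labels) == n, length(batches) == n)
  dimnames(intensities) <- list(as.character(ids), NULL)
  structure(list(grid = grid, intensities = intensities,
                 ids = as.character(ids), labels = as.character(labels),
                 batches = as.character(batches)),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  nl <- sum(!is.na(x$labels))
  cat(sprintf("<spectra_set> %d spectra x %d points, %g-%g cm^-1, %d labeled\n",
              nrow(x$intensities), length(x$grid), min(x$grid), max(x$grid), nl))
  invisible(x)
}

#' Number of spectra in a set
#' @param ds A `spectra_set`.
#' @return Integer count of rows.
#' @export
n_spectra <- function(ds) nrow(ds$intensities)

#' Extract one spectrum from a set
#' @param ds A `spectra_set`.
#' @param i Row index or id.
#' @return A `spectrum`.
#' @export
get_spectrum <- function(ds, i) {
  if (is.character(i)) i <- match(i, ds$ids)
  spectrum(ds$grid, ds$intensities[i, ], id = ds$ids[i])
}

## Delimiter auto-detection among comma / tab / semicolon, from the header line.
detect_sep <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop("no non-comment lines in ", path, call. = FALSE)
  header <- lines[1]
  counts <- vapply(c("," = ",", "\t" = "\t", ";" = ";"),
                   function(s) lengths(regmatches(header, gregexpr(s, header, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0)) stop("could not detect delimiter (comma/tab/semicolon) in ",
                             path, call. = FALSE)
  c(",", "\t", ";")[which.max(counts)]
}

#' Read spectra from wide-format delimited text
#'
#' Column 1 holds the wavenumber axis (cm^-1); every remaining column is one
#' spectrum named by its header. The delimiter is auto-detected among comma,
#' tab and semicolon. An optional label table (columns `id`, `class`, `batch`)
#' attaches class and batch metadata by spectrum id.
#'
#' @param path Path to the spectra file.
#' @param label_path Optional path to the label table.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path, label_path = NULL) {
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("spectra file needs a wavenumber column plus at least one spectrum",
                          call. = FALSE)
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      stop("column '", names(tab)[j], "' of ", path, " is not numeric", call. = FALSE)
    }
  }
  grid <- tab[[1]]
  check_ascending(grid)
  mat <- t(as.matrix(tab[, -1, drop = FALSE]))
  ids <- names(tab)[-1]
  labels <- batches <- NULL
  if (!is.null(label_path)) {
    lsep <- detect_sep(label_path)
    lab <- utils::read.table(label_path, header = TRUE, sep = lsep,
                             check.names = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("id", "class", "batch")
    if (!all(need %in% names(lab))) {
      stop("label file must have columns id, class, batch", call. = FALSE)
    }
    m <- match(ids, lab$id)
    if (anyNA(m)) {
      stop("spectra without a label row: ", paste(ids[is.na(m)], collapse = ", "),
           call. = FALSE)
    }
    extra <- setdiff(lab$id, ids)
    if (length(extra)) {
      stop("label rows without a spectrum column: ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    labels <- lab$class[m]
    batches <- as.character(lab$batch[m])
  }
  spectra_set(grid, mat, ids = ids, labels = labels, batches = batches)
}

#' Write spectra to wide-format delimited text
#'
#' Values are written with 17 significant digits so that a write/read cycle
#' reproduces the doubles bit-exactly.
#'
#' @param ds A `spectra_set`.
#' @param path Output path for the spectra table.
#' @param label_path Optional output path for the label table (id, class, batch).
#' @param sep Field delimiter (comma, tab or semicolon).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path, label_path = NULL, sep = "\t") {
  stopifnot(inherits(ds, "spectra_set"), sep %in% c(",", "\t", ";"))
  header <- paste(c("wavenumber", ds$ids), collapse = sep)
  body <- cbind(sprintf("%.17g", ds$grid),
                t(matrix(sprintf("%.17g", ds$intensities),
                         nrow = nrow(ds$intensities))))
  lines <- c(header, apply(body, 1, paste, collapse = sep))
  writeLines(lines, path)
  if (!is.null(label_path)) {
    lab <- data.frame(id = ds$ids, class = ds$labels, batch = ds$batches,
                      stringsAsFactors = FALSE)
    utils::write.table(lab, label_path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Resample a spectrum onto a new grid by linear interpolation
#'
#' Shared grid points are preserved exactly; extrapolation outside the original
#' range is refused so that zone indices keep a fixed meaning.
#'
#' @param s A `spectrum`.
#' @param target_grid Ascending wavenumbers within the range of `s$grid`.
#' @return A `spectrum` on `target_grid`.
#' @export
resample <- function(s, target_grid) {
  stopifnot(inherits(s, "spectrum"))
  target_grid <- as.numeric(target_grid)
  check_ascending(target_grid)
  if (min(target_grid) < min(s$grid) || max(target_grid) > max(s$grid)) {
    stop("target grid [", min(target_grid), ", ", max(target_grid),
         "] extends beyond the measured range [", min(s$grid), ", ",
         max(s$grid), "]; extrapolation is not supported", call. = FALSE)
  }
  y <- stats::approx(s$grid, s$intensities, xout = target_grid,
                     method = "linear", ties = "ordered")$y
  spectrum(target_grid, y, id = s$id)
}

#' Wrap a prediction function as a model adapter
#'
#' The adapter is the only contract the explainers need from a model: a
#' stateless function mapping a numeric matrix (one intensity vector per row,
#' on `grid`) to an `n x n_classes` matrix of class probabilities.
#'
#' @param predict Function taking an intensity matrix and returning a
#'   probability matrix whose rows sum to 1.
#' @param class_names Ordered class labels, one per output column.
#' @param grid Optional wavenumber grid the model expects.
#' @return An object of class `model_adapter`.
#' @export
model_adapter <- function(predict, class_names, grid = NULL) {
  stopifnot(is.function(predict), length(class_names) >= 1)
  structure(list(predict = predict, class_names = as.character(class_names),
                 grid = grid),
            class = "model_adapter")
}

#' Predict class probabilities through an adapter, with contract checks
#'
#' @param model A `model_adapter`.
#' @param X Intensity matrix (rows = spectra) or a single numeric vector.
#' @return Probability matrix, one row per input row; rows sum to 1 within 1e-6.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "model_adapter"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  P <- model$predict(X)
  P <- as.matrix(P)
  if (nrow(P) != nrow(X) || ncol(P) != length(model$class_names)) {
    stop("model returned a ", nrow(P), "x", ncol(P), " matrix for ",
         nrow(X), " inputs and ", length(model$class_names), " classes",
         call. = FALSE)
  }
  rs <- rowSums(P)
  if (any(!is.finite(rs)) || any(abs(rs - 1) > 1e-6)) {
    stop("model output rows must sum to 1 (max deviation ",
         signif(max(abs(rs - 1)), 3), ")", call. = FALSE)
  }
  colnames(P) <- model$class_names
  P
}

#' Expected model output over a reference set
#'
#' The arithmetic mean of the predicted probability of one class over every
#' spectrum of a reference set: the quantity E\[f(x)\] at which a waterfall
#' explanation starts.
#'
#' @param model A `model_adapter`.
#' @param reference A non-empty `spectra_set` on the model's grid.
#' @param class_index Column index of the class of interest.
#' @return A single probability.
#' @export
expected_value <- function(model, reference, class_index) {
  stopifnot(inherits(reference, "spectra_set"))
  if (n_spectra(reference) == 0) stop("reference set is empty", call. = FALSE)
  class_index <- check_class_index(model, class_index)
  mean(predict_proba(model, reference$intensities)[, class_index])
}

check_class_index <- function(model, class_index) {
  k <- length(model$class_names)
  if (is.character(class_index)) class_index <- match(class_index, model$class_names)
  if (is.na(class_index) || class_index < 1 || class_index > k) {
    stop("class_index must name one of the model's ", k, " classes", call. = FALSE)
  }
  as.integer(class_index)
}
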