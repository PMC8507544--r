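#' Construct a wavenumber axis
#'
#' A wavenumber axis is the shared Raman-shift grid (cm^-1) of a spectrum or
#' spectrum set. Values must be finite, strictly increasing and at least two
#' long; descending input is accepted and reversed.
#'
#' @param values Numeric vector of Raman shifts in cm^-1.
#' @return A numeric vector of class `wavenumber_axis`, sorted ascending.
#' @export
#' @examples
#' wavenumber_axis(seq(600, 1800, by = 2))
wavenumber_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("a wavenumber axis needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("wavenumber axis contains non-finite values", call. = FALSE)
  }
  d <- diff(values)
  if (all(d < 0)) values <- rev(values) else if (any(d <= 0)) {
    stop("wavenumber axis must be strictly monotone", call. = FALSE)
  }
  structure(values, class = "wavenumber_axis")
}

#' Default spectrograph axis
#'
#' The axis of the reference instrument: 1024 samples spanning -34 to
#' 2517 cm^-1 (the spectrograph's pixel-to-wavenumber map is taken as linear
#' over its stated bandwidth).
#'
#' @param n Number of samples.
#' @param lo,hi Axis end points in cm^-1.
#' @return A [wavenumber_axis()].
#' @export
default_axis <- function(n = 1024, lo = -34, hi = 2517) {
  wavenumber_axis(seq(lo, hi, length.out = n))
}

#' Construct a single spectrum
#'
#' @param axis A [wavenumber_axis()] (or numeric vector coerced to one).
#' @param intensities Numeric vector, one value per axis sample.
#' @param id Opaque label for the spectrum.
#' @return An object of class `spectrum`: a list with `axis`, `intensities`,
#'   `id`.
#' @export
new_spectrum <- function(axis, intensities, id = "s1") {
  if (!inherits(axis, "wavenumber_axis")) axis <- wavenumber_axis(axis)
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(axis)) {
    stop("intensities length (", length(intensities),
         ") does not match axis length (", length(axis), ")", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("spectrum intensities contain non-finite values", call. = FALSE)
  }
  structure(list(axis = axis, intensities = intensities,
                 id = as.character(id)),
            class = "spectrum")
}

#' Construct a spectrum set
#'
#' The workhorse container of the package: an `n_spectra x n_channels`
#' intensity matrix over one shared wavenumber axis, with optional per-spectrum
#' class labels and a tibble of per-spectrum metadata (acquisition time, stage
#' position, quality flags, ...).
#'
#' @param axis A [wavenumber_axis()].
#' @param mat Numeric matrix, rows are spectra, columns are axis channels.
#' @param labels Optional character/factor vector of class labels, one per row.
#' @param meta Optional tibble/data frame with one row per spectrum.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(axis, mat, labels = NULL, meta = NULL) {
  if (!inherits(axis, "wavenumber_axis")) axis <- wavenumber_axis(axis)
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (ncol(mat) != length(axis)) {
    stop("matrix has ", ncol(mat), " channels but axis has ", length(axis),
         call. = FALSE)
  }
  if (any(!is.finite(mat))) {
    stop("spectrum set contains non-finite intensities", call. = FALSE)
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(mat)) {
      stop("labels length must equal the number of spectra", call. = FALSE)
    }
    labels <- as.character(labels)
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("s%03d", seq_len(nrow(mat)))
  }
  if (is.null(meta)) {
    meta <- tibble::tibble(id = rownames(mat))
  } else {
    meta <- tibble::as_tibble(meta)
    if (nrow(meta) != nrow(mat)) {
      stop("meta must have one row per spectrum", call. = FALSE)
    }
    if (!"id" %in% names(meta)) meta$id <- rownames(mat)
  }
  structure(list(axis = axis, matrix = mat, labels = labels, meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$matrix), " spectra x ", ncol(x$matrix),
      " channels, ", format(round(min(x$axis), 1)), "-",
      format(round(max(x$axis), 1)), " cm^-1\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("labels: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> '", x$id, "', ", length(x$axis), " channels\n", sep = "")
  invisible(x)
}

#' Number of spectra in a set
#' @param ss A `spectrum_set`.
#' @return Integer count of spectra.
#' @export
n_spectra <- function(ss) nrow(ss$matrix)

#' Extract one spectrum from a set
#' @param ss A `spectrum_set`.
#' @param i Row index or spectrum id.
#' @return A `spectrum`.
#' @export
get_spectrum <- function(ss, i) {
  if (is.character(i)) i <- match(i, rownames(ss$matrix))
  new_spectrum(ss$axis, ss$matrix[i, ], id = rownames(ss$matrix)[i])
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.spectrum_set <- function(x, ...) {
  n <- nrow(x$matrix)
  p <- ncol(x$matrix)
  out <- tibble::tibble(
    spectrum_id = rep(rownames(x$matrix), each = p),
    wavenumber = rep(as.numeric(x$axis), times = n),
    intensity = as.numeric(t(x$matrix))
  )
  if (!is.null(x$labels)) out$label <- rep(x$labels, each = p)
  out
}

#' @export
as_tibble.spectrum <- function(x, ...) {
  tibble::tibble(spectrum_id = x$id, wavenumber = as.numeric(x$axis),
                 intensity = x$intensities)
}

#' Read spectra from a delimited table
#'
#' Two dialects are understood. `"wide"` (the canonical on-disk form): a
#' header row, column 1 named `wavenumber_cm1`, one further column per
#' spectrum. `"long"`: columns `wavenumber`, `intensity`, `spectrum_id`.
#' A JSON sidecar `<path>.json`, when present, restores labels and metadata
#' written by [write_spectra()]. Descending axes are reordered ascending.
#'
#' @param path Path to a CSV (or TSV, inferred from extension) file.
#' @param dialect `"wide"` or `"long"`.
#' @return A [spectrum_set()].
#' @export
read_spectra <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (dialect == "wide") {
    if (length(non_num) > 0) {
      bad <- non_num[1]
      row <- which(is.na(suppressWarnings(as.numeric(df[[bad]]))))[1]
      stop("non-numeric cell in column '", bad, "', row ",
           ifelse(is.na(row), "?", row), call. = FALSE)
    }
    ax <- df[[1]]
    ord <- order(ax)
    axis <- wavenumber_axis(ax[ord])
    mat <- t(as.matrix(df[ord, -1, drop = FALSE]))
    rownames(mat) <- names(df)[-1]
  } else {
    need <- c("wavenumber", "intensity", "spectrum_id")
    if (!all(need %in% names(df))) {
      stop("long dialect needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (!is.numeric(df$wavenumber) || !is.numeric(df$intensity)) {
      stop("non-numeric cell in 'wavenumber' or 'intensity'", call. = FALSE)
    }
    wide <- tidyr::pivot_wider(df, names_from = "spectrum_id",
                               values_from = "intensity")
    if (anyNA(wide)) {
      stop("axis mismatch: spectra do not share a common wavenumber axis",
           call. = FALSE)
    }
    ord <- order(wide$wavenumber)
    axis <- wavenumber_axis(wide$wavenumber[ord])
    mat <- t(as.matrix(wide[ord, -1, drop = FALSE]))
  }
  labels <- NULL
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(sc$labels)) labels <- as.character(sc$labels)
    if (!is.null(sc$meta)) meta <- tibble::as_tibble(sc$meta)
  }
  spectrum_set(axis, mat, labels = labels, meta = meta)
}

#' Write spectra to a delimited table
#'
#' Inverse of [read_spectra()]. Labels and metadata go to a JSON sidecar
#' `<path>.json` so the table itself stays purely numeric.
#'
#' @param ss A `spectrum_set`.
#' @param path Output CSV path.
#' @param dialect `"wide"` or `"long"`.
#' @param sidecar Write the metadata sidecar? Default `TRUE` when labels or
#'   non-trivial metadata are present.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ss, path, dialect = c("wide", "long"),
                          sidecar = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ss, "spectrum_set"))
  if (dialect == "wide") {
    df <- tibble::as_tibble(as.data.frame(t(ss$matrix)))
    names(df) <- rownames(ss$matrix)
    df <- dplyr::bind_cols(tibble::tibble(wavenumber_cm1 = as.numeric(ss$axis)),
                           df)
  } else {
    df <- as_tibble(ss)[, c("wavenumber", "intensity", "spectrum_id")]
  }
  readr::write_csv(df, path, progress = FALSE)
  if (is.null(sidecar)) {
    sidecar <- !is.null(ss$labels) || ncol(ss$meta) > 1
  }
  if (isTRUE(sidecar)) {
    jsonlite::write_json(list(labels = ss$labels, meta = ss$meta),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Crop to the fingerprint region
#'
#' Retains exactly the channels with `lo <= wavenumber <= hi` (closed
#' interval). The 600-1800 cm^-1 default is the biomolecular fingerprint
#' window used for all downstream statistics.
#'
#' @param ss A `spectrum_set` or `spectrum`.
#' @param lo,hi Interval bounds in cm^-1.
#' @return Object of the same class restricted to the interval.
#' @export
crop_fingerprint <- function(ss, lo = 600, hi = 1800) {
  UseMethod("crop_fingerprint")
}

#' @export
crop_fingerprint.spectrum_set <- function(ss, lo = 600, hi = 1800) {
  keep <- fingerprint_keep(ss$axis, lo, hi)
  out <- ss
  out$axis <- wavenumber_axis(as.numeric(ss$axis)[keep])
  out$matrix <- ss$matrix[, keep, drop = FALSE]
  out
}

#' @export
crop_fingerprint.spectrum <- function(ss, lo = 600, hi = 1800) {
  keep <- fingerprint_keep(ss$axis, lo, hi)
  new_spectrum(as.numeric(ss$axis)[keep], ss$intensities[keep], id = ss$id)
}

fingerprint_keep <- function(axis, lo, hi) {
  if (!(lo < hi)) stop("crop bounds must satisfy lo < hi", call. = FALSE)
  keep <- which(axis >= lo & axis <= hi)
  if (length(keep) < 2) {
    stop("crop interval [", lo, ", ", hi, "] overlaps fewer than 2 channels",
         call. = FALSE)
  }
  keep
}

#' Pearson correlation of two intensity vectors
#'
#' The quality primitive behind reference ranking and the r >= 0.99 cull.
#' Errors on constant input, where the correlation is undefined.
#'
#' @param a,b Equal-length numeric vectors (length >= 3).
#' @return Product-moment correlation in \[-1, 1\].
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(a, b)
}
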