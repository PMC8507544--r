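# Spectral pre-processing pipeline: matched-spectrum cosmic-ray removal,
# reference construction, EMSC correction, Savitzky-Golay denoising and the
# Pearson quality cull.

# running median with reflection padding, so the end channels are detrended
# like interior ones
runmed_reflect <- function(x, k) {
  n <- length(x)
  h <- (k - 1) / 2
  if (n < k + 1) return(stats::runmed(x, min(k, n - (n + 1) %% 2)))
  pad <- c(rev(x[2:(h + 1)]), x, rev(x[(n - h):(n - 1)]))
  stats::runmed(pad, k)[(h + 1):(h + n)]
}

#' Remove cosmic-ray spikes by matched-spectrum substitution
#'
#' Each spectrum is modelled from its closest matches in the dataset: the
#' most correlated spectra (correlation computed with suspect channels
#' patched out) are ranked by how clean their scaled residual is, and the
#' best two, together with a cubic polynomial, are fitted to the spectrum by
#' least squares. The fit residual is detrended with a running median
#' (width 21, blind to spikes up to `max_width` channels wide) and channels
#' exceeding `k_sigma` robust standard deviations - per-channel MAD across
#' spectra, since shot noise makes strong bands noisier than quiet channels -
#' in contiguous runs of at most `max_width` channels are replaced with the
#' matched-model values. Two passes are run so a spike sitting in a
#' spectrum's best match cannot survive; clean data pass through
#' bit-identically.
#'
#' @param ss A `spectrum_set` with at least 2 spectra.
#' @param k_sigma Detection threshold in robust standard deviations.
#' @param max_width Maximum spike width in channels; longer runs are treated
#'   as genuine structure and left alone.
#' @param passes Number of detection/replacement passes.
#' @return A list: `spectra` (corrected `spectrum_set`) and `report` (tibble
#'   of class `cosmic_ray_report`: `spectrum_id, channel, match_id, pass`).
#' @export
remove_cosmic_rays <- function(ss, k_sigma = 8, max_width = 3, passes = 2) {
  stopifnot(inherits(ss, "spectrum_set"))
  n <- n_spectra(ss)
  if (n < 2) {
    stop("cosmic-ray removal needs at least 2 spectra; for a single ",
         "spectrum use a median-filter fallback (runmed)", call. = FALSE)
  }
  mat <- ss$matrix
  p <- ncol(mat)
  ids <- rownames(mat)
  rows <- list()
  for (pass in seq_len(passes)) {
    src <- mat                      # pass detects against the pass-start state
    # suspect pre-mask: narrow departures from a running median. With enough
    # spectra the departure is judged per channel against the dataset
    # (median/MAD across spectra), so sharp Raman bands - which always stick
    # out of their own running median - are not mistaken for spikes; tiny
    # sets fall back to a per-spectrum global scale.
    rm_resid <- t(apply(src, 1, function(x) x - runmed_reflect(x, 9)))
    if (n >= 15) {
      med_c <- apply(rm_resid, 2, stats::median)
      sig_c <- apply(rm_resid, 2, stats::mad)
      sig_c <- pmax(sig_c, 0.2 * stats::median(sig_c))
      suspects <- abs(sweep(rm_resid, 2, med_c)) >
        matrix(6 * sig_c, n, p, byrow = TRUE)
    } else {
      suspects <- t(apply(rm_resid, 1, function(r) {
        s <- stats::mad(r)
        if (s <= 0) s <- stats::sd(r)
        if (!is.finite(s) || s <= 0) return(rep(FALSE, p))
        abs(r) > 6 * s
      }))
    }
    # proxy matrix with suspects patched by the running median, for matching
    proxy <- src
    for (i in seq_len(n)) {
      if (any(suspects[i, ])) {
        sm <- runmed_reflect(src[i, ], 9)
        proxy[i, suspects[i, ]] <- sm[suspects[i, ]]
      }
    }
    cmat <- suppressWarnings(stats::cor(t(proxy)))
    diag(cmat) <- -Inf
    # stage 1: per spectrum, fit the two closest matches (plus a cubic
    # Legendre term for smooth baseline mismatch) and keep the detrended
    # residual; stage 2 thresholds those residuals against a per-channel
    # robust noise scale, since shot noise makes strong-band channels far
    # noisier than the quiet parts of the axis
    leg <- legendre_basis(seq_len(p), 3)
    det_mat <- matrix(NA_real_, n, p)
    fit_mat <- matrix(NA_real_, n, p)
    good_mat <- matrix(TRUE, n, p)
    patched_mat <- matrix(FALSE, n, p)   # channels patched in the matches
    match_of <- integer(n)
    for (i in seq_len(n)) {
      # rank the most correlated spectra by how clean their scaled residual
      # is outside the suspect channels: correlation is scale-free, so it
      # alone can pair spectra whose sharp bands differ in amplitude, which
      # would mimic a narrow spike
      cand <- order(cmat[i, ], decreasing = TRUE)[seq_len(min(6, n - 1))]
      worst <- vapply(cand, function(j) {
        good_j <- !suspects[i, ] & !suspects[j, ]
        if (sum(good_j) < 10) good_j <- rep(TRUE, p)
        a_j <- sum(src[i, good_j] * proxy[j, good_j]) /
          sum(proxy[j, good_j]^2)
        det_j <- src[i, ] - a_j * proxy[j, ]
        det_j <- det_j - runmed_reflect(det_j, 21)
        sig_j <- stats::mad(det_j[good_j])
        if (sig_j > 0) max(abs(det_j[good_j])) / sig_j else Inf
      }, numeric(1))
      cand <- cand[order(worst)]
      j1 <- cand[1]
      j2 <- if (length(cand) > 1) cand[2] else NULL
      good <- !suspects[i, ]
      # matches enter the model suspect-patched, so a spike in a match can
      # never leak into the fit, the residual, or the replacement values
      D <- cbind(proxy[j1, ], leg)
      if (!is.null(j2)) {
        # span the two closest spectra, so residual mismatch in the cell vs
        # substrate weights (not just overall scale) cancels as well
        D <- cbind(proxy[j2, ], D)
      }
      if (sum(good) < 10) good <- rep(TRUE, p)
      coef <- qr.coef(qr(D[good, , drop = FALSE]), src[i, good])
      coef[is.na(coef)] <- 0
      fitted <- drop(D %*% coef)
      det_r <- src[i, ] - fitted
      det_mat[i, ] <- det_r - runmed_reflect(det_r, 21)
      fit_mat[i, ] <- fitted
      good_mat[i, ] <- good
      patched_mat[i, ] <- if (is.null(j2)) suspects[j1, ] else
        suspects[j1, ] | suspects[j2, ]
      match_of[i] <- j1
    }
    # per-channel noise scale across spectra (robust to the rare spikes);
    # small sets fall back to each spectrum's global robust scale
    sigma_global <- vapply(seq_len(n), function(i) {
      stats::mad(det_mat[i, good_mat[i, ]])
    }, numeric(1))
    if (n >= 15) {
      sigma_ch <- apply(det_mat, 2, stats::mad)
      floor_sig <- 0.2 * stats::median(sigma_global)
      sigma_ch <- pmax(sigma_ch, floor_sig)
    } else {
      sigma_ch <- NULL
    }
    changed <- FALSE
    for (i in seq_len(n)) {
      if (!is.null(sigma_ch)) {
        # a spectrum without a close match in the set has residuals inflated
        # across the board; scale its threshold up accordingly (never down)
        s_i <- stats::mad(det_mat[i, good_mat[i, ]] /
                            sigma_ch[good_mat[i, ]])
        sig <- sigma_ch * max(1, s_i)
      } else {
        # floor at numerical precision so exact fits never flag rounding
        sig <- rep(max(sigma_global[i], 1e-8 * max(abs(src))), p)
      }
      # cosmic rays are strictly positive charge deposits; a spike sitting
      # in a match can only drive the residual negative, so one-sided
      # thresholding makes match contamination harmless. A flag must also
      # either stand out of its own spectrum's running median (pre-suspect)
      # or clear the threshold with half again as much margin: residual band
      # mismatch in amplitude-outlier spectra can brush k sigma, but unlike
      # a real spike it is neither a narrow in-spectrum feature nor huge.
      flag <- det_mat[i, ] > k_sigma * sig &
        (suspects[i, ] | det_mat[i, ] > 1.5 * k_sigma * sig)
      if (is.null(sigma_ch)) {
        # tiny sets have no per-channel scale: with near-duplicate spectra
        # the global MAD can collapse to ~0, so channels synthesised into
        # the match model (patched suspects) must not be flagged off it
        flag <- flag & !patched_mat[i, ]
      }
      if (!any(flag)) next
      runs <- rle(flag)
      keep <- runs
      keep$values <- runs$values & runs$lengths <= max_width
      flag <- inverse.rle(keep)
      if (!any(flag)) next
      ch <- which(flag)
      mat[i, ch] <- fit_mat[i, ch]
      changed <- TRUE
      rows[[length(rows) + 1]] <- tibble::tibble(
        spectrum_id = ids[i], channel = ch, match_id = ids[match_of[i]],
        pass = pass)
    }
    if (!changed) break
  }
  report <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(spectrum_id = character(0), channel = integer(0),
                   match_id = character(0), pass = integer(0))
  class(report) <- c("cosmic_ray_report", class(tibble::tibble()))
  out <- ss
  out$matrix <- mat
  list(spectra = out, report = report)
}

#' Build the cell reference spectrum
#'
#' The reference is the unsmoothed mean of the `k` highest-quality spectra.
#' Quality is ranked by Pearson correlation against the channel-wise median
#' spectrum of the set (robust to spikes and outliers); an SNR ranking
#' (total signal over MAD of the second difference) is available as an
#' alternative.
#'
#' @param ss A `spectrum_set` with at least `k` spectra, typically recorded
#'   on a substrate that is flat in the fingerprint region (CaF2).
#' @param k Number of top-quality spectra to average.
#' @param rank `"median_cor"` or `"snr"`.
#' @return A `spectrum` (id `"reference"`); the indices of the selected
#'   spectra are stored in `attr(, "selected")`.
#' @export
build_reference <- function(ss, k = 50, rank = c("median_cor", "snr")) {
  rank <- match.arg(rank)
  stopifnot(inherits(ss, "spectrum_set"))
  n <- n_spectra(ss)
  if (n < k) {
    stop("need at least k = ", k, " spectra, got ", n, call. = FALSE)
  }
  if (rank == "median_cor") {
    med <- apply(ss$matrix, 2, stats::median)
    score <- apply(ss$matrix, 1, function(x) stats::cor(x, med))
  } else {
    score <- apply(ss$matrix, 1, function(x) {
      sum(x) / max(stats::mad(diff(x, differences = 2)),
                   .Machine$double.eps)
    })
  }
  top <- order(score, decreasing = TRUE)[seq_len(k)]
  ref <- new_spectrum(ss$axis, colMeans(ss$matrix[top, , drop = FALSE]),
                      id = "reference")
  attr(ref, "selected") <- sort(top)
  ref
}

#' Build the substrate (glass) reference spectrum
#'
#' Channel-wise mean of the substrate spectra followed by Savitzky-Golay
#' smoothing with polynomial order 3 and window 9.
#'
#' @param glass A `spectrum_set` of substrate-only spectra.
#' @param window,order Savitzky-Golay parameters.
#' @return A `spectrum` (id `"substrate"`).
#' @export
build_substrate_reference <- function(glass, window = 9, order = 3) {
  stopifnot(inherits(glass, "spectrum_set"), n_spectra(glass) >= 1)
  m <- new_spectrum(glass$axis, colMeans(glass$matrix), id = "substrate")
  savitzky_golay(m, window = window, order = order)
}

legendre_basis <- function(axis, order) {
  u <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  P <- matrix(0, length(u), order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- u
  if (order >= 2) {
    for (m in 2:order) {
      P[, m + 1] <- ((2 * m - 1) * u * P[, m] - (m - 1) * P[, m - 1]) / m
    }
  }
  P
}

#' EMSC baseline / substrate correction of one spectrum
#'
#' Ordinary least squares decomposition of the raw spectrum into a cell
#' reference component (weight `cr`), an optional substrate component
#' (weight `cb`), and an order-`N` polynomial baseline, followed by removal
#' of the background and division by `cr`:
#' `X = (X0 - cb*B - sum_m cm*Pm) / cr`.
#' The polynomial basis is Legendre on the axis rescaled to \[-1, 1\] for
#' conditioning; with no substrate (`substrate = NULL`, the CaF2 case)
#' `cb` is fixed at 0. Division by `cr` normalises the corrected spectrum to
#' the scale of the reference.
#'
#' @param x0 Raw `spectrum`.
#' @param ref Cell reference `spectrum` on the same axis.
#' @param substrate Substrate `spectrum` on the same axis, or `NULL`.
#' @param order Polynomial order N (default 5).
#' @param cr_tol Smallest admissible reference weight.
#' @param max_condition Condition-number bound on the design matrix.
#' @return A list of class `emsc_result`: `corrected` (spectrum), `cr`,
#'   `cb`, `cm` (length N+1), `residual_norm`.
#' @export
emsc_correct <- function(x0, ref, substrate = NULL, order = 5,
                         cr_tol = 1e-6, max_condition = 1e10) {
  stopifnot(inherits(x0, "spectrum"), inherits(ref, "spectrum"))
  ax <- as.numeric(x0$axis)
  if (length(ax) != length(ref$axis) ||
      max(abs(ax - as.numeric(ref$axis))) > 1e-9) {
    stop("spectrum and reference are on different axes", call. = FALSE)
  }
  if (stats::sd(ref$intensities) == 0) {
    stop("reference spectrum is constant", call. = FALSE)
  }
  P <- legendre_basis(ax, order)
  comp_names <- c("reference",
                  if (!is.null(substrate)) "substrate",
                  paste0("P", 0:order))
  D <- cbind(ref$intensities,
             if (!is.null(substrate)) substrate$intensities,
             P)
  colnames(D) <- comp_names
  # column-equilibrated condition / collinearity check
  Dn <- sweep(D, 2, sqrt(colSums(D^2)), `/`)
  sv <- svd(Dn, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > max_condition) {
    offender <- collinear_component(Dn, comp_names)
    stop("collinear EMSC design: component '", offender,
         "' lies in the span of the others", call. = FALSE)
  }
  coef <- qr.solve(D, x0$intensities)
  cr <- coef[1]
  cb <- if (!is.null(substrate)) coef[2] else 0
  cm <- coef[(length(coef) - order):length(coef)]
  if (cr <= cr_tol) {
    stop("degenerate EMSC fit: reference weight cr = ", signif(cr, 3),
         " <= ", cr_tol, call. = FALSE)
  }
  background <- cb * (if (!is.null(substrate)) substrate$intensities else 0) +
    drop(P %*% cm)
  corrected <- new_spectrum(x0$axis, (x0$intensities - background) / cr,
                            id = x0$id)
  structure(list(corrected = corrected, cr = unname(cr), cb = unname(cb),
                 cm = unname(cm),
                 residual_norm = sqrt(sum((drop(D %*% coef) -
                                             x0$intensities)^2))),
            class = "emsc_result")
}

collinear_component <- function(Dn, nms) {
  r2 <- vapply(seq_len(ncol(Dn)), function(j) {
    fit <- stats::lm.fit(Dn[, -j, drop = FALSE], Dn[, j])
    1 - sum(fit$residuals^2) / sum((Dn[, j] - mean(Dn[, j]))^2)
  }, numeric(1))
  nms[which.max(r2)]
}

#' EMSC-correct every spectrum in a set
#'
#' @param ss A `spectrum_set`.
#' @inheritParams emsc_correct
#' @return A list: `spectra` (corrected `spectrum_set`) and `coefficients`
#'   (tibble `id, cr, cb, residual_norm` plus one column per polynomial
#'   coefficient).
#' @export
emsc_correct_set <- function(ss, ref, substrate = NULL, order = 5,
                             cr_tol = 1e-6) {
  n <- n_spectra(ss)
  out <- ss
  coefs <- vector("list", n)
  for (i in seq_len(n)) {
    r <- emsc_correct(get_spectrum(ss, i), ref, substrate, order, cr_tol)
    out$matrix[i, ] <- r$corrected$intensities
    cm <- as.list(r$cm)
    names(cm) <- paste0("c", seq_along(cm) - 1)
    coefs[[i]] <- tibble::tibble(id = rownames(ss$matrix)[i], cr = r$cr,
                                 cb = r$cb,
                                 residual_norm = r$residual_norm, !!!cm)
  }
  list(spectra = out, coefficients = dplyr::bind_rows(coefs))
}

sg_weights <- function(window, order) {
  h <- (window - 1) / 2
  x <- -h:h
  A <- outer(x, 0:order, `^`)
  # first row of the pseudo-inverse = weights evaluating the fit at centre
  solve(crossprod(A), t(A))[1, ]
}

#' Savitzky-Golay smoothing
#'
#' Centred local least-squares polynomial smoothing. Interior channels use
#' the standard convolution weights; each edge channel is refit on its
#' truncated window (the available channels within `(window-1)/2` of it), so
#' polynomials up to the filter order pass through unchanged everywhere.
#'
#' @param s A `spectrum` (or numeric vector).
#' @param window Odd window length, greater than `order`.
#' @param order Polynomial order.
#' @return Smoothed object of the same type.
#' @export
savitzky_golay <- function(s, window = 7, order = 3) {
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window <= order) stop("window must exceed the polynomial order",
                            call. = FALSE)
  x <- if (inherits(s, "spectrum")) s$intensities else as.numeric(s)
  n <- length(x)
  if (n < window) stop("spectrum shorter than the window", call. = FALSE)
  h <- (window - 1) / 2
  w <- sg_weights(window, order)
  sm <- stats::filter(x, rev(w), sides = 2)
  sm <- as.numeric(sm)
  for (i in c(seq_len(h), (n - h + 1):n)) {
    idx <- max(1, i - h):min(n, i + h)
    u <- idx - i
    A <- outer(u, 0:order, `^`)
    beta <- qr.solve(A, x[idx])
    sm[i] <- beta[1]
  }
  if (inherits(s, "spectrum")) new_spectrum(s$axis, sm, id = s$id) else sm
}

#' Savitzky-Golay denoise a spectrum set
#'
#' @param ss A `spectrum_set`.
#' @inheritParams savitzky_golay
#' @return The denoised `spectrum_set`.
#' @export
savitzky_golay_set <- function(ss, window = 7, order = 3) {
  out <- ss
  out$matrix <- t(apply(ss$matrix, 1, savitzky_golay, window = window,
                        order = order))
  dimnames(out$matrix) <- dimnames(ss$matrix)
  out
}

#' Cull low-quality spectra by Pearson correlation with the reference
#'
#' Spectra with `r >= threshold` against the cell reference are retained
#' (the boundary is kept). Intended to run after EMSC correction and
#' denoising, on the fingerprint region.
#'
#' @param ss A `spectrum_set`.
#' @param ref Reference `spectrum` on the same axis.
#' @param threshold Retention threshold on r (default 0.99).
#' @return A list: `spectra` (retained subset) and `report` (tibble of class
#'   `quality_report` with `id, r, retained`; the retention fraction is in
#'   `attr(, "retention")`).
#' @export
quality_cull <- function(ss, ref, threshold = 0.99) {
  stopifnot(inherits(ss, "spectrum_set"), inherits(ref, "spectrum"))
  if (ncol(ss$matrix) != length(ref$axis)) {
    stop("set and reference are on different axes", call. = FALSE)
  }
  r <- apply(ss$matrix, 1, function(x) stats::cor(x, ref$intensities))
  retained <- r >= threshold
  report <- tibble::tibble(id = rownames(ss$matrix), r = as.numeric(r),
                           retained = retained)
  attr(report, "retention") <- mean(retained)
  class(report) <- c("quality_report", class(tibble::tibble()))
  out <- ss
  out$matrix <- ss$matrix[retained, , drop = FALSE]
  if (!is.null(ss$labels)) out$labels <- ss$labels[retained]
  out$meta <- ss$meta[retained, , drop = FALSE]
  list(spectra = out, report = report)
}
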