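# Image-analysis engine: variance autofocus, mosaic stitching, bright-spot
# candidate detection, isolation filtering, route ordering, pixel->stage
# geometry. Pixel coordinates are 0-based (row, col); stage coordinates are
# micrometres with x right / y up. The affine map owns all sign conventions.

#' Image contrast metric for autofocus
#'
#' The default contrast is the variance over the mean of pixel intensities
#' (population variance), which is maximal when the sample sits in the
#' bright-spot plane. The squared coefficient of variation is available as an
#' alternative definition.
#'
#' @param img An [image_tile()] or a numeric matrix.
#' @param definition `"var_over_mean"` (sigma^2 / mu) or `"cv_squared"`
#'   ((sigma / mu)^2).
#' @return A single non-negative contrast value.
#' @export
variance_metric <- function(img, definition = c("var_over_mean",
                                                "cv_squared")) {
  definition <- match.arg(definition)
  px <- if (inherits(img, "image_tile")) img$pixels else as.matrix(img)
  if (length(px) == 0) stop("empty image", call. = FALSE)
  mu <- mean(px)
  if (mu <= 0) stop("variance metric undefined for mean <= 0", call. = FALSE)
  v <- mean((px - mu)^2)   # population variance
  if (definition == "var_over_mean") v / mu else v / mu^2
}

#' Build a variance profile from a z-stack
#'
#' @param z Focus positions (um), strictly monotone.
#' @param metric Contrast value per position.
#' @return A tibble of class `variance_profile` with columns `z`, `metric`.
#' @export
variance_profile <- function(z, metric) {
  stopifnot(length(z) == length(metric))
  d <- diff(z)
  if (!(all(d > 0) || all(d < 0))) {
    stop("z positions must be strictly monotone", call. = FALSE)
  }
  out <- tibble::tibble(z = as.numeric(z), metric = as.numeric(metric))
  class(out) <- c("variance_profile", class(out))
  out
}

#' Locate the bright-spot and focal planes from a variance profile
#'
#' The bright-spot plane is the interior global maximum of the contrast
#' metric; the focal plane is the interior local minimum closest to it (ties
#' broken toward smaller |z|). A maximum on the scan boundary means the scan
#' range did not bracket the bright-spot plane and is an error.
#'
#' @param profile A [variance_profile()] (or data frame with `z`, `metric`).
#' @return A list of class `focus_result`: `z_bright_spot`, `z_focus`,
#'   `profile`.
#' @export
autofocus <- function(profile) {
  z <- profile$z
  m <- profile$metric
  if (length(z) < 5) stop("autofocus needs at least 5 z samples",
                          call. = FALSE)
  ord <- order(z)
  z <- z[ord]
  m <- m[ord]
  n <- length(z)
  imax <- which.max(m)
  if (imax == 1 || imax == n) {
    stop("scan range too small: contrast maximum lies on the scan boundary",
         call. = FALSE)
  }
  interior <- 2:(n - 1)
  is_min <- vapply(interior, function(i) {
    m[i] <= m[i - 1] && m[i] <= m[i + 1]
  }, logical(1))
  mins <- interior[is_min]
  if (length(mins) == 0) {
    stop("no interior local minimum of the variance profile", call. = FALSE)
  }
  dist <- abs(z[mins] - z[imax])
  best <- mins[dist == min(dist)]
  if (length(best) > 1) best <- best[which.min(abs(z[best]))]
  structure(list(z_bright_spot = z[imax], z_focus = z[best],
                 profile = variance_profile(z, m)),
            class = "focus_result")
}

#' @export
print.focus_result <- function(x, ...) {
  cat("<focus_result> bright-spot plane ", x$z_bright_spot,
      " um, focal plane ", x$z_focus, " um\n", sep = "")
  invisible(x)
}

# Extract the nominally overlapping regions of two equal-size tiles, where
# b(r, c) ~= a(r + dr, c + dc) for rel = (dr, dc). Returns NULL when the
# nominal layout leaves fewer than 4 shared pixels along either axis.
overlap_strips <- function(a, b, rel) {
  n <- dim(a)
  ra <- max(1, 1 + rel[1]):min(n[1], n[1] + rel[1])
  ca <- max(1, 1 + rel[2]):min(n[2], n[2] + rel[2])
  if (length(ra) < 4 || length(ca) < 4) return(NULL)
  list(a = a[ra, ca, drop = FALSE],
       b = b[ra - rel[1], ca - rel[2], drop = FALSE])
}

# Phase correlation of two equal-size images. Returns the translation
# (dr, dc) such that b(r, c) ~= a(r + dr, c + dc), with sub-pixel parabolic
# refinement, plus the ratio of the correlation peak to the strongest peak
# outside its 5x5 neighbourhood.
phase_correlate <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cp <- fa * Conj(fb)
  mag <- Mod(cp)
  mag[mag < .Machine$double.eps] <- 1
  r <- Re(stats::fft(cp / mag, inverse = TRUE)) / length(a)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  n <- dim(r)
  # wrap indices to signed shifts
  wrap <- function(i, len) ifelse(i - 1 > len / 2, i - 1 - len, i - 1)
  dr <- wrap(pk[1], n[1])
  dc <- wrap(pk[2], n[2])
  # sub-pixel parabola through the peak and its axial neighbours
  sub <- function(idx, len, axis_val) {
    im <- (idx - 2) %% len + 1
    ip <- idx %% len + 1
    y0 <- if (axis_val == 1) r[im, pk[2]] else r[pk[1], im]
    y2 <- if (axis_val == 1) r[ip, pk[2]] else r[pk[1], ip]
    y1 <- r[pk[1], pk[2]]
    den <- y0 - 2 * y1 + y2
    if (abs(den) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / den
  }
  dr <- dr + sub(pk[1], n[1], 1)
  dc <- dc + sub(pk[2], n[2], 2)
  # peak ratio against the best peak away from the main one
  mask <- r
  rows <- ((pk[1] - 3):(pk[1] + 1)) %% n[1] + 1
  cols <- ((pk[2] - 3):(pk[2] + 1)) %% n[2] + 1
  mask[rows, cols] <- -Inf
  second <- max(mask)
  ratio <- if (second <= 0) Inf else max(r) / second
  list(shift = c(dr, dc), ratio = ratio)
}

#' Stitch a grid of overlapping tiles into a mosaic
#'
#' Translation-only registration: nominal per-tile pixel offsets come from
#' the commanded stage positions and the pixel size; each tile is then
#' refined against its left and top neighbours by phase correlation, falling
#' back to the nominal offset whenever the correlation peak ratio is below
#' `min_peak_ratio` (featureless overlap). Overlaps are blended by a
#' feathered average.
#'
#' @param tiles List of [image_tile()]s sharing `pixel_size` and `z`, whose
#'   stage positions form a rectangular grid.
#' @param nominal_overlap Nominal overlap fraction between neighbouring
#'   tiles (used only for sanity checks).
#' @param min_peak_ratio Phase-correlation confidence threshold.
#' @return A list of class `mosaic`: `mosaic` (matrix), `offsets` (tibble
#'   `tile, row_off, col_off, stage_x, stage_y, refined`), `pixel_size`.
#' @export
stitch_grid <- function(tiles, nominal_overlap = 0.1, min_peak_ratio = 3) {
  stopifnot(length(tiles) >= 1)
  ps <- vapply(tiles, function(t) t$pixel_size, numeric(1))
  if (length(unique(ps)) != 1) {
    stop("tiles do not share a pixel size", call. = FALSE)
  }
  ps <- ps[1]
  sx <- vapply(tiles, function(t) t$stage_xy[1], numeric(1))
  sy <- vapply(tiles, function(t) t$stage_xy[2], numeric(1))
  ux <- sort(unique(round(sx / ps)))
  uy <- sort(unique(round(sy / ps)), decreasing = TRUE)  # y up -> row down
  gi <- match(round(sy / ps), uy)  # grid row
  gj <- match(round(sx / ps), ux)  # grid col
  if (anyNA(gi) || anyNA(gj) ||
      anyDuplicated(cbind(gi, gj)) ||
      length(tiles) != length(ux) * length(uy)) {
    stop("stage positions do not form a complete rectangular grid",
         call. = FALSE)
  }
  dims <- dim(tiles[[1]]$pixels)
  # nominal 0-based top-left offsets from stage coordinates
  nom_row <- (max(sy) - sy) / ps
  nom_col <- (sx - min(sx)) / ps
  off <- cbind(nom_row, nom_col)
  refined <- rep(FALSE, length(tiles))
  idx_at <- function(i, j) which(gi == i & gj == j)
  for (i in seq_along(uy)) {
    for (j in seq_along(ux)) {
      k <- idx_at(i, j)
      ests <- NULL
      for (nb in list(c(i, j - 1), c(i - 1, j))) {
        if (nb[1] < 1 || nb[2] < 1) next
        k0 <- idx_at(nb[1], nb[2])
        nominal_rel <- c(nom_row[k], nom_col[k]) -
          c(nom_row[k0], nom_col[k0])
        # correlate only the nominally overlapping strips: they share
        # almost all their content, so the peak is sharp even at 10% overlap
        st <- overlap_strips(tiles[[k0]]$pixels, tiles[[k]]$pixels,
                             round(nominal_rel))
        if (is.null(st)) next
        pc <- phase_correlate(st$a, st$b)
        if (pc$ratio >= min_peak_ratio &&
            all(abs(pc$shift) < pmax(4, 0.25 * dim(st$a)))) {
          ests <- rbind(ests, off[k0, ] + nominal_rel + pc$shift)
        }
      }
      if (!is.null(ests)) {
        off[k, ] <- colMeans(ests)
        refined[k] <- TRUE
      }
    }
  }
  off <- sweep(off, 2, apply(off, 2, min))
  off <- unname(off)
  h <- ceiling(max(off[, 1])) + dims[1]
  w <- ceiling(max(off[, 2])) + dims[2]
  acc <- matrix(0, h, w)
  wt <- matrix(0, h, w)
  feather <- {
    r <- seq_len(dims[1])
    c <- seq_len(dims[2])
    outer(pmin(r, rev(r)), pmin(c, rev(c)), pmin)
  }
  for (k in seq_along(tiles)) {
    r0 <- round(off[k, 1])
    c0 <- round(off[k, 2])
    rows <- (r0 + 1):(r0 + dims[1])
    cols <- (c0 + 1):(c0 + dims[2])
    acc[rows, cols] <- acc[rows, cols] + tiles[[k]]$pixels * feather
    wt[rows, cols] <- wt[rows, cols] + feather
  }
  mosaic <- acc / pmax(wt, .Machine$double.eps)
  offsets <- tibble::tibble(tile = seq_along(tiles),
                            row_off = off[, 1], col_off = off[, 2],
                            stage_x = sx, stage_y = sy, refined = refined)
  structure(list(mosaic = mosaic, offsets = offsets, pixel_size = ps,
                 tile_dims = dims),
            class = "mosaic")
}

gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    idx <- pmin(pmax(seq(1 - r, n + r), 1), n)   # replicate edges
    mp <- m[idx, , drop = FALSE]
    out <- apply(mp, 2, function(col) stats::filter(col, k, sides = 2))
    out[(r + 1):(r + n), , drop = FALSE]
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Detect bright-spot candidates in a mosaic
#'
#' Gaussian-smooths the image, then returns local maxima exceeding
#' `background + prominence * (max - background)` (background is the median
#' of the smoothed image) that are at least `min_distance` pixels apart;
#' plateau maxima are reduced to their centroid.
#'
#' @param mosaic A `mosaic` from [stitch_grid()], an [image_tile()], or a
#'   numeric matrix.
#' @param sigma Gaussian pre-filter width in pixels (about the spot radius).
#' @param min_distance Minimum candidate spacing in pixels.
#' @param prominence Threshold as a fraction of the smoothed dynamic range.
#' @return A tibble of class `candidate_set` with 0-based `row`, `col`,
#'   `score` (smoothed peak intensity) and `isolation` (distance to the
#'   nearest other candidate, px; `Inf` for a single candidate).
#' @export
detect_bright_spots <- function(mosaic, sigma = 4, min_distance = 8,
                                prominence = 0.25) {
  stopifnot(sigma >= 0, min_distance >= 1)
  img <- if (inherits(mosaic, "mosaic")) mosaic$mosaic
         else if (inherits(mosaic, "image_tile")) mosaic$pixels
         else as.matrix(mosaic)
  sm <- gaussian_smooth(img, sigma)
  bg <- stats::median(sm)
  thr <- bg + prominence * (max(sm) - bg)
  n <- nrow(sm)
  m <- ncol(sm)
  # a featureless (noise-only) field has no detectable spots: require the
  # dynamic range to clear the smoothed noise floor
  if (max(sm) <= bg || max(sm) - bg < 5 * stats::mad(sm) ||
      n < 3 || m < 3) {
    return(empty_candidates())
  }
  core <- sm[2:(n - 1), 2:(m - 1)]
  is_peak <- core > thr
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      is_peak <- is_peak &
        core >= sm[2:(n - 1) + dr, 2:(m - 1) + dc, drop = FALSE]
    }
  }
  pk <- which(is_peak, arr.ind = TRUE)
  if (nrow(pk) == 0) return(empty_candidates())
  pts <- tibble::tibble(row = pk[, 1] + 1, col = pk[, 2] + 1,
                        score = sm[cbind(pk[, 1] + 1, pk[, 2] + 1)])
  # collapse plateaus / near-coincident maxima inside one smoothing radius
  pts <- collapse_plateaus(pts, radius = max(1, sigma))
  # greedy min-distance suppression on descending score
  pts <- pts[order(-pts$score, pts$row, pts$col), ]
  kept <- integer(0)
  for (i in seq_len(nrow(pts))) {
    if (length(kept) == 0) {
      kept <- i
    } else {
      d <- sqrt((pts$row[kept] - pts$row[i])^2 +
                  (pts$col[kept] - pts$col[i])^2)
      if (min(d) >= min_distance) kept <- c(kept, i)
    }
  }
  pts <- pts[kept, ]
  out <- tibble::tibble(row = pts$row - 1, col = pts$col - 1,
                        score = pts$score)
  out$isolation <- nn_distance(out$row, out$col)
  class(out) <- c("candidate_set", class(tibble::tibble()))
  out
}

empty_candidates <- function() {
  out <- tibble::tibble(row = numeric(0), col = numeric(0),
                        score = numeric(0), isolation = numeric(0))
  class(out) <- c("candidate_set", class(tibble::tibble()))
  out
}

collapse_plateaus <- function(pts, radius) {
  if (nrow(pts) <= 1) return(pts)
  used <- rep(FALSE, nrow(pts))
  out <- list()
  ord <- order(-pts$score, pts$row, pts$col)
  for (i in ord) {
    if (used[i]) next
    d <- sqrt((pts$row - pts$row[i])^2 + (pts$col - pts$col[i])^2)
    grp <- which(!used & d <= radius & pts$score >= pts$score[i] - 1e-9)
    used[grp] <- TRUE
    out[[length(out) + 1]] <- tibble::tibble(
      row = mean(pts$row[grp]), col = mean(pts$col[grp]),
      score = max(pts$score[grp]))
  }
  dplyr::bind_rows(out)
}

nn_distance <- function(x, y) {
  n <- length(x)
  if (n < 2) return(rep(Inf, n))
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Keep the most isolated candidates
#'
#' Isolation is the Euclidean distance to the nearest other candidate in the
#' full set. The `n_keep` candidates with the largest isolation are kept
#' (clustered cells, which risk double targeting, are dropped first). Ties
#' are broken by higher score, then lower row, then lower column.
#'
#' @param cs A `candidate_set`.
#' @param n_keep Number of candidates to keep; `n_keep >= nrow(cs)` returns
#'   all.
#' @return A `candidate_set` with recomputed isolation among survivors.
#' @export
select_isolated <- function(cs, n_keep) {
  stopifnot(n_keep >= 1)
  if (nrow(cs) <= n_keep) return(cs)
  iso <- nn_distance(cs$row, cs$col)
  ord <- order(-iso, -cs$score, cs$row, cs$col)
  out <- cs[sort(ord[seq_len(n_keep)]), ]
  out$isolation <- nn_distance(out$row, out$col)
  out
}

#' Order targets with a greedy nearest-neighbour route
#'
#' Repeatedly appends the unvisited point closest to the last visited one,
#' seeded by `start`, to limit total stage travel (ties go to the lowest
#' index).
#'
#' @param points Data frame with stage coordinates `x_um`, `y_um` (other
#'   columns are carried along).
#' @param start Starting stage position `c(x, y)` (not itself a target).
#' @return A tibble of class `target_list`: the input rows reordered, with an
#'   `order` column prepended.
#' @export
order_route <- function(points, start = c(0, 0)) {
  stopifnot(nrow(points) >= 1, all(c("x_um", "y_um") %in% names(points)))
  n <- nrow(points)
  visited <- logical(n)
  route <- integer(n)
  cur <- as.numeric(start)
  for (k in seq_len(n)) {
    d <- sqrt((points$x_um - cur[1])^2 + (points$y_um - cur[2])^2)
    d[visited] <- Inf
    nxt <- which.min(d)     # ties -> lowest index
    route[k] <- nxt
    visited[nxt] <- TRUE
    cur <- c(points$x_um[nxt], points$y_um[nxt])
  }
  out <- tibble::as_tibble(points[route, , drop = FALSE])
  out <- dplyr::bind_cols(tibble::tibble(order = seq_len(n)), out)
  class(out) <- c("target_list", class(tibble::tibble()))
  out
}

route_length <- function(points, start = c(0, 0)) {
  xs <- c(start[1], points$x_um)
  ys <- c(start[2], points$y_um)
  sum(sqrt(diff(xs)^2 + diff(ys)^2))
}

#' Fit the pixel-to-stage affine transform
#'
#' Least-squares affine map from 0-based mosaic pixel coordinates (row, col)
#' to stage coordinates (x, y in um), accommodating per-axis scale, axis
#' flips, rotation and skew. Needs at least three non-collinear
#' correspondences.
#'
#' @param pixel_pts Matrix/data frame of pixel coordinates (`row`, `col`).
#' @param stage_pts Matrix/data frame of matching stage coordinates
#'   (`x`, `y`).
#' @return A list of class `affine_map_2d`: `A` (2x2, um/px), `t`
#'   (translation, um), `rms_residual`.
#' @export
fit_pixel_to_stage <- function(pixel_pts, stage_pts) {
  P <- as.matrix(pixel_pts)[, 1:2, drop = FALSE]
  S <- as.matrix(stage_pts)[, 1:2, drop = FALSE]
  if (nrow(P) != nrow(S)) stop("correspondence counts differ", call. = FALSE)
  if (nrow(P) < 3) stop("need at least 3 correspondences", call. = FALSE)
  D <- cbind(1, P)
  if (qr(D)$rank < 3) {
    stop("correspondences are collinear: affine map underdetermined",
         call. = FALSE)
  }
  fit <- qr.solve(D, S)          # 3 x 2: rows = (intercept, row, col)
  A <- t(fit[2:3, , drop = FALSE])
  tvec <- as.numeric(fit[1, ])
  if (abs(det(A)) < 1e-12) {
    stop("degenerate affine map: linear part is singular", call. = FALSE)
  }
  res <- D %*% fit - S
  structure(list(A = A, t = tvec,
                 rms_residual = sqrt(mean(res^2))),
            class = "affine_map_2d")
}

#' Map pixel coordinates to stage coordinates
#'
#' @param map An `affine_map_2d` from [fit_pixel_to_stage()].
#' @param pixel_pts Matrix/data frame of 0-based (row, col) coordinates.
#' @return A tibble with `x_um`, `y_um`.
#' @export
pixel_to_stage <- function(map, pixel_pts) {
  P <- as.matrix(pixel_pts)[, 1:2, drop = FALSE]
  if (nrow(P) == 0) return(tibble::tibble(x_um = numeric(0),
                                          y_um = numeric(0)))
  S <- t(map$A %*% t(P)) + matrix(map$t, nrow(P), 2, byrow = TRUE)
  tibble::tibble(x_um = S[, 1], y_um = S[, 2])
}

#' @export
print.affine_map_2d <- function(x, ...) {
  cat("<affine_map_2d> um/px linear part:\n")
  print(round(x$A, 6))
  cat("translation (um):", round(x$t, 3),
      " rms residual:", signif(x$rms_residual, 3), "\n")
  invisible(x)
}

#' Translate a target list by the laser-spot offset
#'
#' The laser spot is displaced from the imaging axis by a calibrated,
#' configuration-supplied offset; every stage coordinate is translated
#' uniformly and the acquisition order is preserved.
#'
#' @param tl A `target_list`.
#' @param offset `c(dx, dy)` in micrometres.
#' @return The translated `target_list`.
#' @export
apply_laser_offset <- function(tl, offset) {
  stopifnot(length(offset) == 2, all(is.finite(offset)))
  tl$x_um <- tl$x_um + offset[1]
  tl$y_um <- tl$y_um + offset[2]
  tl
}
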