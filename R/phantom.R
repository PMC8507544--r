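# Synthetic slide + spectrum generators and the simulated instrument.
# Everything here is a pure function of (parameters, seed), so ground truth is
# always available to the targeting, preprocessing and classification tests.

derive_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 65011 + 1) * 32771 + 7919 *
                as.numeric(i)) %% 2147483647)
}

#' CCD camera noise model
#'
#' Defaults follow a deep-depletion spectroscopy CCD operated at -80 C in
#' full-vertical-bin mode: read noise 4 electrons per spectral sample and mean
#' dark current 0.0512 electrons/second/sample; gain 1 count per electron.
#'
#' @param read_noise_sd Read noise standard deviation (electrons/sample).
#' @param dark_current Mean dark current (electrons/second/sample).
#' @param gain Conversion gain (counts/electron).
#' @return A `camera_model` list.
#' @export
camera_model <- function(read_noise_sd = 4, dark_current = 0.0512, gain = 1) {
  stopifnot(read_noise_sd >= 0, dark_current >= 0, gain >= 0)
  structure(list(read_noise_sd = read_noise_sd, dark_current = dark_current,
                 gain = gain),
            class = "camera_model")
}

# Default cell Raman band table (count-rate units, counts/s at band centre).
# Bands are those recurring in bladder-cell work: DNA backbone (680, 789,
# 1093, 1490), phenylalanine (1003), tyrosine (1170), amide III (1245),
# CH2/CH3 deformation (1303, 1449), amide I (1660), etc.
default_peak_table <- function() {
  tibble::tibble(
    center = c(680, 750, 789, 830, 1003, 1093, 1170, 1245, 1303, 1340,
               1370, 1424, 1449, 1490, 1580, 1660),
    width  = c(10, 9, 10, 12, 8, 14, 10, 18, 12, 12, 10, 12, 14, 12, 12, 16),
    amp    = 3 * c(10, 8, 16, 7, 30, 12, 8, 14, 16, 12, 8, 8, 24, 10, 10, 26)
  )
}

#' Spectral phantom parameters
#'
#' Describes the generative model for synthetic cell spectra: a shared cell
#' band table with class contrast confined to a few discriminating DNA/protein
#' bands, a broad glass-substrate profile strongest around 1050-1150 cm^-1, a
#' random low-order polynomial autofluorescence baseline, lognormal cell and
#' substrate weights, and a cosmic-ray process.
#'
#' @param peaks Tibble `center, width, amp` of Gaussian cell bands
#'   (counts/s units).
#' @param discriminating Band centres (cm^-1) whose amplitude differs between
#'   the two classes.
#' @param band_contrast Fractional amplitude contrast at the discriminating
#'   bands; the first class gets `1 + c/2`, the second `1 - c/2`.
#' @param classes Character vector of the two class labels (high grade first).
#' @param glass Tibble `center, width, amp` of broad glass humps (counts/s).
#' @param baseline_range 4 x 2 matrix of uniform ranges for polynomial
#'   baseline coefficients c0..c3 on the axis rescaled to \[-1, 1\]
#'   (counts/s).
#' @param cr_sdlog,cb_sdlog Lognormal sd of the cell / substrate weights
#'   (meanlog 0).
#' @param cosmic_rate Cosmic-ray arrival rate (events/second/spectrum).
#' @param cosmic_amp_range Spike amplitude range in units of the local noise
#'   standard deviation.
#' @param cosmic_widths Possible spike widths in channels.
#' @return A `spectral_phantom_params` list.
#' @export
spectral_phantom_params <- function(
    peaks = default_peak_table(),
    discriminating = c(789, 1003, 1490),
    band_contrast = 0.15,
    classes = c("HT1197", "RT112"),
    glass = tibble::tibble(center = c(550, 800, 1100),
                           width = c(120, 100, 60),
                           amp = 3 * c(30, 12, 25)),
    baseline_range = 3 * rbind(c(5, 15), c(-5, 5), c(-3, 3), c(-2, 2)),
    cr_sdlog = 0.25,
    cb_sdlog = 0.2,
    cosmic_rate = 0.01,
    cosmic_amp_range = c(20, 200),
    cosmic_widths = 1:3) {
  stopifnot(all(peaks$width > 0), cosmic_rate >= 0, length(classes) == 2,
            band_contrast >= 0, nrow(baseline_range) >= 1)
  structure(list(peaks = peaks, discriminating = discriminating,
                 band_contrast = band_contrast, classes = classes,
                 glass = glass, baseline_range = baseline_range,
                 cr_sdlog = cr_sdlog, cb_sdlog = cb_sdlog,
                 cosmic_rate = cosmic_rate,
                 cosmic_amp_range = cosmic_amp_range,
                 cosmic_widths = cosmic_widths),
            class = "spectral_phantom_params")
}

gaussian_bands <- function(axis, tab) {
  out <- numeric(length(axis))
  for (i in seq_len(nrow(tab))) {
    out <- out + tab$amp[i] * exp(-(axis - tab$center[i])^2 /
                                    (2 * tab$width[i]^2))
  }
  out
}

#' Noise-free class signature (count rate)
#'
#' The pure cell component of the generative model for one class: Gaussian
#' bands from the phantom's peak table, with the discriminating bands scaled
#' by the class contrast. Units are counts/s; multiply by the acquisition
#' time for expected counts.
#'
#' @param class One of `p$classes`.
#' @param p A [spectral_phantom_params()].
#' @param axis A [wavenumber_axis()].
#' @return Numeric count-rate vector over `axis`.
#' @export
class_signature <- function(class, p, axis) {
  tab <- p$peaks
  idx <- match(class, p$classes)
  if (is.na(idx)) stop("unknown class: ", class, call. = FALSE)
  f <- if (idx == 1) 1 + p$band_contrast / 2 else 1 - p$band_contrast / 2
  disc <- tab$center %in% p$discriminating
  tab$amp[disc] <- tab$amp[disc] * f
  gaussian_bands(as.numeric(axis), tab)
}

glass_signature <- function(p, axis) {
  gaussian_bands(as.numeric(axis), p$glass)
}

baseline_poly <- function(coef, axis) {
  u <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
  drop(outer(u, seq_along(coef) - 1, `^`) %*% coef)
}

#' Generate one synthetic cell (or glass-only) spectrum
#'
#' Raw counts are modelled as the weighted superposition
#' `cr * R_class + cb * Glass + baseline` (all in counts/s, scaled by
#' `t_acq`), plus dark charge, Poisson shot noise on the accumulated
#' electrons, Gaussian read noise, and narrow cosmic-ray spikes with recorded
#' ground-truth channels.
#'
#' @param class Class label from `p$classes`, or `NULL` for a glass-only
#'   (substrate) spectrum with `cr = 0`.
#' @param p A [spectral_phantom_params()].
#' @param cam A [camera_model()].
#' @param t_acq Acquisition time in seconds.
#' @param axis A [wavenumber_axis()].
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param noise Include dark/shot/read noise? `FALSE` gives the deterministic
#'   expectation with `cr = 1`, `cb` drawn as usual unless also disabled.
#' @param cosmic Include cosmic rays?
#' @param id Spectrum id.
#' @return A `spectrum`; ground truth (`cr`, `cb`, `cosmic_channels`, class)
#'   is stored in `attr(, "truth")`.
#' @export
generate_spectrum <- function(class, p, cam = camera_model(), t_acq = 10,
                              axis = default_axis(), seed = 1, noise = TRUE,
                              cosmic = TRUE, id = "s1") {
  stopifnot(t_acq > 0)
  ax <- as.numeric(axis)
  withr::with_seed(seed, {
    cr <- if (is.null(class)) 0 else stats::rlnorm(1, 0, p$cr_sdlog)
    cb <- stats::rlnorm(1, 0, p$cb_sdlog)
    bl_coef <- apply(p$baseline_range, 1,
                     function(r) stats::runif(1, r[1], r[2]))
    if (!noise) {
      cr <- if (is.null(class)) 0 else 1
    }
    cell <- if (is.null(class)) 0 else cr * class_signature(class, p, ax)
    bl <- baseline_poly(bl_coef, ax)
    bl <- bl + max(0, 5 - min(bl))   # autofluorescence never goes dark
    rate <- cell + cb * glass_signature(p, ax) + bl
    lambda <- pmax(t_acq * rate, 0)
    dark <- cam$dark_current * t_acq
    if (noise) {
      counts <- cam$gain * (stats::rpois(length(ax), lambda + dark) +
                              stats::rnorm(length(ax), 0, cam$read_noise_sd))
    } else {
      counts <- cam$gain * (lambda + dark)
    }
    cosmic_channels <- integer(0)
    if (cosmic && p$cosmic_rate > 0) {
      n_cr <- stats::rpois(1, p$cosmic_rate * t_acq)
      sigma_local <- cam$gain * sqrt(lambda + dark + cam$read_noise_sd^2)
      for (k in seq_len(n_cr)) {
        w <- sample(p$cosmic_widths, 1)
        # distinct events stay > max spike width apart so ground-truth
        # events never merge into one wide run
        for (try in 1:50) {
          start <- sample.int(length(ax) - w + 1, 1)
          chans <- start:(start + w - 1)
          if (length(cosmic_channels) == 0 ||
              min(abs(outer(chans, cosmic_channels, `-`))) > 3) break
        }
        amps <- stats::runif(w, p$cosmic_amp_range[1], p$cosmic_amp_range[2])
        counts[chans] <- counts[chans] + amps * sigma_local[chans]
        cosmic_channels <- union(cosmic_channels, chans)
      }
    }
    s <- new_spectrum(axis, counts, id = id)
    attr(s, "truth") <- list(class = class, cr = cr, cb = cb,
                             cosmic_channels = sort(cosmic_channels))
    s
  })
}

#' Generate a labelled two-class spectrum set
#'
#' Convenience wrapper producing `n_per_class` spectra for each class in
#' `p$classes`, with ground truth (weights, cosmic-ray channels) in the
#' metadata tibble.
#'
#' @inheritParams generate_spectrum
#' @param n_per_class Spectra per class.
#' @return A `spectrum_set` with `labels` and truth columns in `meta`.
#' @export
generate_spectrum_set <- function(n_per_class, p = spectral_phantom_params(),
                                  cam = camera_model(), t_acq = 10,
                                  axis = default_axis(), seed = 1,
                                  noise = TRUE, cosmic = TRUE) {
  classes <- rep(p$classes, each = n_per_class)
  n <- length(classes)
  mat <- matrix(0, n, length(axis))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_spectrum(classes[i], p, cam, t_acq, axis,
                           seed = derive_seed(seed, i), noise = noise,
                           cosmic = cosmic, id = sprintf("s%04d", i))
    mat[i, ] <- s$intensities
    truth[[i]] <- attr(s, "truth")
  }
  rownames(mat) <- sprintf("s%04d", seq_len(n))
  meta <- tibble::tibble(
    id = rownames(mat),
    t_acq = t_acq,
    cr = vapply(truth, `[[`, numeric(1), "cr"),
    cb = vapply(truth, `[[`, numeric(1), "cb"),
    cosmic_channels = lapply(truth, `[[`, "cosmic_channels")
  )
  spectrum_set(axis, mat, labels = classes, meta = meta)
}

#' Generate glass-only substrate spectra
#'
#' @inheritParams generate_spectrum_set
#' @param n Number of substrate spectra (a screening run records 20, each
#'   30 s).
#' @return A `spectrum_set` without labels.
#' @export
generate_glass_set <- function(n = 20, p = spectral_phantom_params(),
                               cam = camera_model(), t_acq = 30,
                               axis = default_axis(), seed = 1,
                               noise = TRUE) {
  mat <- matrix(0, n, length(axis))
  for (i in seq_len(n)) {
    s <- generate_spectrum(NULL, p, cam, t_acq, axis,
                           seed = derive_seed(seed, 100000 + i),
                           noise = noise, cosmic = FALSE,
                           id = sprintf("glass%03d", i))
    mat[i, ] <- s$intensities
  }
  rownames(mat) <- sprintf("glass%03d", seq_len(n))
  spectrum_set(axis, mat,
               meta = tibble::tibble(id = rownames(mat), t_acq = t_acq))
}

#' Slide phantom geometry / optics parameters
#'
#' @param field_extent Side of the square stage field (micrometres).
#' @param preset `"thinprep"` (bright-spot plane 14 um above focus) or
#'   `"adherent"` (50 um); sets `z_spot` unless given explicitly.
#' @param z_spot Displacement of the bright-spot plane from focus (um).
#' @param background Background illumination level (counts).
#' @param amp_range Bright-spot peak amplitude range (counts).
#' @param spot_radius_range Bright-spot Gaussian radius range (um).
#' @param zeta Axial extent of the bright-spot Gaussian z-envelope (um).
#' @param isolation_um Minimum spacing enforced between non-clustered nuclei.
#' @param pair_um Centre distance of clustered pairs.
#' @param margin Clearance kept between nuclei and the field edge (um).
#' @param ring_frac,ring_radius,ring_width,ring_zc,ring_zsigma Parameters of
#'   the faint defocus ring each cell shows away from the bright-spot plane
#'   (fraction of spot amplitude; ring radius and Gaussian shell width, um;
#'   saturation and decay scales of its z-dependence, um).
#' @return A `slide_params` list.
#' @export
slide_params <- function(field_extent = 220,
                         preset = c("thinprep", "adherent"),
                         z_spot = NULL, background = 100,
                         amp_range = c(120, 200),
                         spot_radius_range = c(1.5, 2.5), zeta = 5,
                         isolation_um = 15, pair_um = 4, margin = 10,
                         ring_frac = 0.25, ring_radius = 6, ring_width = 1.5,
                         ring_zc = 10, ring_zsigma = 12) {
  preset <- match.arg(preset)
  if (is.null(z_spot)) z_spot <- if (preset == "thinprep") 14 else 50
  stopifnot(z_spot != 0, field_extent > 0, all(amp_range > 0))
  structure(list(field_extent = field_extent, preset = preset,
                 z_spot = z_spot, background = background,
                 amp_range = amp_range,
                 spot_radius_range = spot_radius_range, zeta = zeta,
                 isolation_um = isolation_um, pair_um = pair_um,
                 margin = margin, ring_frac = ring_frac,
                 ring_radius = ring_radius, ring_width = ring_width,
                 ring_zc = ring_zc, ring_zsigma = ring_zsigma),
            class = "slide_params")
}

#' Generate a ground-truth slide phantom
#'
#' Places `n_nuclei` nuclei in the stage field. A fraction `clustering` of
#' them form close pairs (centre distance `params$pair_um`, mimicking the
#' clustered cells that get double-targeted on real slides); all other
#' spacings respect `params$isolation_um`. Classes are assigned at random
#' from `sp$classes`.
#'
#' @param n_nuclei Number of nuclei (>= 1).
#' @param clustering Fraction of nuclei placed in close pairs, in \[0, 1\].
#' @param params A [slide_params()].
#' @param sp A [spectral_phantom_params()] supplying the class labels.
#' @param seed Integer seed.
#' @return A `slide_phantom`: `params`, `seed`, and a `nuclei` tibble with
#'   `x_um, y_um, class, amplitude, radius_um, clustered`.
#' @export
generate_slide <- function(n_nuclei, clustering = 0, params = slide_params(),
                           sp = spectral_phantom_params(), seed = 1) {
  stopifnot(n_nuclei >= 0, clustering >= 0, clustering <= 1)
  n_pairs <- floor(round(clustering * n_nuclei) / 2)
  n_seeds <- n_nuclei - n_pairs          # pair anchors + singles
  lo <- params$margin
  hi <- params$field_extent - params$margin
  if (hi <= lo) stop("field too small for the configured margin",
                     call. = FALSE)
  withr::with_seed(seed, {
    pts <- matrix(NA_real_, 0, 2)
    attempts <- 0
    while (nrow(pts) < n_seeds) {
      cand <- stats::runif(2, lo, hi)
      ok <- nrow(pts) == 0 ||
        min(sqrt(colSums((t(pts) - cand)^2))) >= params$isolation_um
      if (ok) pts <- rbind(pts, cand)
      attempts <- attempts + 1
      if (attempts > 20000 * n_seeds) {
        stop("placement failed: field too small for ", n_nuclei,
             " nuclei at ", params$isolation_um, " um isolation",
             call. = FALSE)
      }
    }
    clustered <- rep(FALSE, n_seeds)
    partner <- matrix(NA_real_, 0, 2)
    for (k in seq_len(n_pairs)) {
      placed <- FALSE
      for (try in 1:500) {
        th <- stats::runif(1, 0, 2 * pi)
        cand <- pts[k, ] + params$pair_um * c(cos(th), sin(th))
        inside <- all(cand >= lo & cand <= hi)
        # a partner is close only to its own anchor: it keeps the isolation
        # distance from every other nucleus
        others <- rbind(pts[-k, , drop = FALSE], partner)
        clear <- nrow(others) == 0 ||
          min(sqrt(colSums((t(others) - cand)^2))) >= params$isolation_um
        if (inside && clear) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("placement failed: could not isolate a clustered pair",
             call. = FALSE)
      }
      partner <- rbind(partner, cand)
      clustered[k] <- TRUE
    }
    all_pts <- rbind(pts, partner)
    n <- nrow(all_pts)
    nuclei <- tibble::tibble(
      nucleus = seq_len(n),
      x_um = all_pts[, 1],
      y_um = all_pts[, 2],
      class = sample(sp$classes, n, replace = TRUE),
      amplitude = stats::runif(n, params$amp_range[1], params$amp_range[2]),
      radius_um = stats::runif(n, params$spot_radius_range[1],
                               params$spot_radius_range[2]),
      clustered = c(clustered, rep(TRUE, n_pairs))
    )
  })
  structure(list(params = params, nuclei = nuclei, seed = seed),
            class = "slide_phantom")
}

#' Construct an image tile
#'
#' @param pixels Non-negative numeric matrix (row 1 is the top of the field).
#' @param stage_xy Commanded stage position of the tile centre (um; x right,
#'   y up).
#' @param z Focus offset at which the tile was taken (um).
#' @param pixel_size Micrometres per pixel.
#' @return An `image_tile`.
#' @export
image_tile <- function(pixels, stage_xy, z, pixel_size) {
  pixels <- as.matrix(pixels)
  stopifnot(pixel_size > 0, all(pixels >= 0), length(stage_xy) == 2)
  structure(list(pixels = pixels, stage_xy = as.numeric(stage_xy), z = z,
                 pixel_size = pixel_size),
            class = "image_tile")
}

#' Render a bright-field tile of a slide phantom
#'
#' Phenomenological microlens-effect rendering: each in-view nucleus
#' contributes an isotropic Gaussian bright spot whose amplitude follows a
#' Gaussian envelope in z centred on the bright-spot plane `z_spot`, plus a
#' faint defocus ring that vanishes at focus (z = 0) and decays far from
#' both planes. Poisson shot noise and Gaussian read noise come from the
#' camera model.
#'
#' @param ph A `slide_phantom`.
#' @param cam A [camera_model()].
#' @param stage_xy Tile-centre stage position (um).
#' @param z Focus offset (um).
#' @param fov Tile size in pixels, `c(rows, cols)`.
#' @param pixel_size Micrometres per pixel.
#' @param seed Seed for the noise draw.
#' @param noise Add camera noise?
#' @return An [image_tile()].
#' @export
render_image <- function(ph, cam = camera_model(), stage_xy = c(0, 0), z = 0,
                         fov = c(256, 256), pixel_size = 0.5, seed = 1,
                         noise = TRUE) {
  stopifnot(all(fov > 0), pixel_size > 0)
  pr <- ph$params
  nr <- fov[1]
  nc <- fov[2]
  # pixel-centre stage coordinates: x grows with column, y falls with row
  px_x <- stage_xy[1] + (seq_len(nc) - (nc + 1) / 2) * pixel_size
  px_y <- stage_xy[2] + ((nr + 1) / 2 - seq_len(nr)) * pixel_size
  img <- matrix(pr$background, nr, nc)
  spot_env <- exp(-(z - pr$z_spot)^2 / (2 * pr$zeta^2))
  ring_env <- pr$ring_frac * (z^2 / (z^2 + pr$ring_zc^2)) *
    exp(-z^2 / (2 * pr$ring_zsigma^2))
  half_view <- max(abs(px_x[c(1, nc)] - stage_xy[1])) + 4 * pr$ring_radius
  nuc <- ph$nuclei
  for (i in seq_len(nrow(nuc))) {
    if (abs(nuc$x_um[i] - stage_xy[1]) > half_view ||
        abs(nuc$y_um[i] - stage_xy[2]) > half_view) next
    dx2 <- (px_x - nuc$x_um[i])^2
    dy2 <- (px_y - nuc$y_um[i])^2
    d2 <- outer(dy2, dx2, `+`)
    spot <- nuc$amplitude[i] * spot_env *
      exp(-d2 / (2 * nuc$radius_um[i]^2))
    ring <- nuc$amplitude[i] * ring_env *
      exp(-(sqrt(d2) - pr$ring_radius)^2 / (2 * pr$ring_width^2))
    img <- img + spot + ring
  }
  if (noise) {
    img <- withr::with_seed(seed, {
      matrix(cam$gain * (stats::rpois(length(img), pmax(img, 0)) +
                           stats::rnorm(length(img), 0, cam$read_noise_sd)),
             nr, nc)
    })
    img <- pmax(img, 0)
  }
  image_tile(img, stage_xy, z, pixel_size)
}

#' Write / read an image tile as TIFF
#'
#' Pixel intensities are stored as 32-bit float TIFF; stage metadata goes to a
#' JSON sidecar so round-trips are lossless.
#'
#' @param tile An [image_tile()].
#' @param path Output `.tif` path.
#' @return `path` (write) or an `image_tile` (read).
#' @export
write_tile <- function(tile, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF output", call. = FALSE)
  }
  tiff::writeTIFF(tile$pixels / max(tile$pixels, 1), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(list(stage_xy = tile$stage_xy, z = tile$z,
                            pixel_size = tile$pixel_size,
                            scale = max(tile$pixels, 1)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tile
#' @export
read_tile <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF input", call. = FALSE)
  }
  px <- tiff::readTIFF(path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  image_tile(px * sc$scale, sc$stage_xy, sc$z, sc$pixel_size)
}

#' Simulated microscope / Raman instrument
#'
#' Stands in for the stage + lamp + laser + CCD stack behind a minimal
#' contract: `move_stage(x, y)`, `set_z(z)`, `snap_image()`,
#' `acquire_spectrum(t_acq)`, `position()`. Stage motion is quantised to the
#' encoder resolution (0.1 um) and perturbed by repeatability jitter
#' (0.25 um, 3 sigma). `acquire_spectrum()` returns the class spectrum of
#' the nucleus nearest the laser point if within `capture_radius`, else a
#' glass-plus-baseline spectrum. Identical call sequences under the same seed
#' are identical.
#'
#' @param ph A `slide_phantom`.
#' @param cam A [camera_model()].
#' @param sp A [spectral_phantom_params()].
#' @param axis Spectral axis.
#' @param fov,pixel_size Imaging geometry passed to [render_image()].
#' @param travel Stage travel range (um), applied to both axes.
#' @param laser_offset True displacement of the laser spot from the imaging
#'   centre (um); a calibrated copy is exposed as `$laser_offset` the way a
#'   real rig records its alignment.
#' @param capture_radius Maximum laser-to-nucleus distance that still probes
#'   the nucleus (um).
#' @param resolution_um,repeat_um Stage quantisation and repeatability.
#' @param seed Master seed for all instrument noise.
#' @return An environment of class `sim_instrument`.
#' @export
simulated_instrument <- function(ph, cam = camera_model(),
                                 sp = spectral_phantom_params(),
                                 axis = default_axis(),
                                 fov = c(256, 256), pixel_size = 0.5,
                                 travel = NULL, laser_offset = c(4.5, -3.2),
                                 capture_radius = 3, resolution_um = 0.1,
                                 repeat_um = 0.25, seed = 1) {
  if (is.null(travel)) travel <- c(-100, ph$params$field_extent + 100)
  self <- new.env(parent = emptyenv())
  self$ph <- ph
  self$cam <- cam
  self$sp <- sp
  self$axis <- axis
  self$fov <- fov
  self$pixel_size <- pixel_size
  self$travel <- travel
  self$laser_offset <- laser_offset
  self$capture_radius <- capture_radius
  self$pos <- c(0, 0)      # actual (jittered) position
  self$cmd <- c(0, 0)      # last commanded position
  self$z <- 0
  self$seed <- seed
  self$counter <- 0L
  self$n_acquired <- 0L

  bump <- function() {
    self$counter <- self$counter + 1L
    derive_seed(self$seed, self$counter)
  }

  self$move_stage <- function(x, y) {
    if (any(c(x, y) < travel[1]) || any(c(x, y) > travel[2])) {
      stop("stage limit: (", x, ", ", y, ") outside travel range [",
           travel[1], ", ", travel[2], "] um", call. = FALSE)
    }
    q <- round(c(x, y) / resolution_um) * resolution_um
    s <- bump()
    jit <- withr::with_seed(s, stats::rnorm(2, 0, repeat_um / 3))
    self$cmd <- c(x, y)
    self$pos <- q + jit
    invisible(self$pos)
  }
  self$set_z <- function(z) {
    self$z <- z
    invisible(z)
  }
  self$snap_image <- function() {
    render_image(self$ph, self$cam, stage_xy = self$pos, z = self$z,
                 fov = self$fov, pixel_size = self$pixel_size, seed = bump())
  }
  self$acquire_spectrum <- function(t_acq = 10) {
    laser <- self$pos + self$laser_offset
    nuc <- self$ph$nuclei
    d <- sqrt((nuc$x_um - laser[1])^2 + (nuc$y_um - laser[2])^2)
    i <- which.min(d)
    self$n_acquired <- self$n_acquired + 1L
    id <- sprintf("acq%04d", self$n_acquired)
    if (length(d) > 0 && d[i] <= self$capture_radius) {
      s <- generate_spectrum(nuc$class[i], self$sp, self$cam, t_acq,
                             self$axis, seed = bump(), id = id)
      attr(s, "truth")$nucleus <- nuc$nucleus[i]
      attr(s, "truth")$dist_um <- d[i]
    } else {
      s <- generate_spectrum(NULL, self$sp, self$cam, t_acq, self$axis,
                             seed = bump(), id = id)
      attr(s, "truth")$nucleus <- NA_integer_
      attr(s, "truth")$dist_um <- if (length(d)) d[i] else NA_real_
    }
    s
  }
  self$position <- function() self$pos
  class(self) <- "sim_instrument"
  self
}

#' @export
print.sim_instrument <- function(x, ...) {
  cat("<sim_instrument> ", nrow(x$ph$nuclei), " nuclei, field ",
      x$ph$params$field_extent, " um, z_spot ", x$ph$params$z_spot,
      " um\n", sep = "")
  invisible(x)
}
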