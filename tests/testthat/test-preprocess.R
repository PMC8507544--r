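test_that("a spike in one of two identical spectra is restored exactly", {
  withr::with_seed(2, base <- abs(rnorm(200, 100, 10)))
  m <- rbind(base, base)
  rownames(m) <- c("a", "b")
  sigma <- mad(diff(base)) / sqrt(2)
  spiked <- m
  spiked["a", 77] <- spiked["a", 77] + 50 * sigma
  ss <- spectrum_set(seq(600, 1800, length.out = 200), spiked)
  res <- remove_cosmic_rays(ss)
  expect_equal(unname(res$spectra$matrix["a", 77]), base[77])
  expect_identical(res$spectra$matrix[, -77], ss$matrix[, -77])
  expect_equal(res$report$channel, 77)
  expect_equal(res$report$match_id, "b")
})

test_that("clean data pass through cosmic-ray removal bit-identically", {
  ss <- generate_spectrum_set(20, p = quiet_params(), seed = 3)
  res <- remove_cosmic_rays(ss)
  expect_identical(res$spectra$matrix, ss$matrix)
  expect_equal(nrow(res$report), 0)
  expect_error(remove_cosmic_rays(spectrum_set(1:5, matrix(1:5, 1))),
               "at least 2")
})

test_that("ground-truth spikes are fully recalled with no false positives", {
  p <- spectral_phantom_params(cosmic_rate = 0.15)
  ss <- generate_spectrum_set(50, p = p, seed = 14)   # 100 spectra
  truth <- ss$meta$cosmic_channels
  res <- remove_cosmic_rays(ss)
  flagged <- split(res$report$channel, res$report$spectrum_id)
  tp <- fp <- fn <- 0
  touched <- matrix(FALSE, nrow(ss$matrix), ncol(ss$matrix))
  for (i in seq_len(n_spectra(ss))) {
    id <- rownames(ss$matrix)[i]
    f <- unique(flagged[[id]])
    tr <- truth[[i]]
    tp <- tp + length(intersect(f, tr))
    fp <- fp + length(setdiff(f, tr))
    fn <- fn + length(setdiff(tr, f))
    touched[i, f] <- TRUE
  }
  expect_equal(fn, 0)        # recall 1.0
  expect_equal(fp, 0)        # no false positives
  expect_gt(tp, 50)
  # unflagged channels are bitwise untouched
  expect_identical(res$spectra$matrix[!touched], ss$matrix[!touched])
})

test_that("reference construction averages the highest-quality spectra", {
  ax <- seq(600, 1800, length.out = 150)
  base <- 100 + 50 * exp(-(ax - 1003)^2 / 128)
  m <- matrix(rep(base, 10), 10, byrow = TRUE)
  ss <- spectrum_set(ax, m)
  expect_equal(build_reference(ss, k = 5)$intensities, base)
  # k = n gives the plain mean
  withr::with_seed(8, mr <- m + rnorm(length(m), 0, 1))
  ssr <- spectrum_set(ax, mr)
  expect_equal(build_reference(ssr, k = 10)$intensities, colMeans(mr))
  expect_error(build_reference(ssr, k = 50), "at least k")
  # 60 clean + 40 heavily corrupted: the corrupted never make the top 50
  withr::with_seed(9, {
    clean <- matrix(rep(base, 60), 60, byrow = TRUE) +
      rnorm(60 * 150, 0, 1)
    bad <- matrix(rep(base, 40), 40, byrow = TRUE) +
      rnorm(40 * 150, 0, 40)
  })
  both <- spectrum_set(ax, rbind(clean, bad))
  ref <- build_reference(both, k = 50)
  expect_true(all(attr(ref, "selected") <= 60))
})

test_that("substrate reference is the smoothed mean and preserves cubics", {
  ax <- seq(600, 1800, length.out = 120)
  const <- spectrum_set(ax, matrix(7, 1, 120))
  expect_equal(build_substrate_reference(const)$intensities, rep(7, 120))
  # linearity: mean of two spectra equals the jointly processed pair
  withr::with_seed(10, {
    a <- runif(120, 50, 60)
    b <- runif(120, 70, 90)
  })
  joint <- build_substrate_reference(spectrum_set(ax, rbind(a, b)))
  half <- build_substrate_reference(spectrum_set(ax, rbind((a + b) / 2)))
  expect_equal(joint$intensities, half$intensities, tolerance = 1e-12)
  # a cubic profile passes through SG(3, 9) unchanged
  u <- seq(-1, 1, length.out = 120)
  cub <- 40 + 5 * u - 3 * u^2 + 2 * u^3
  out <- build_substrate_reference(spectrum_set(ax, rbind(cub)))
  expect_lt(max(abs(out$intensities - cub)[5:116]), 1e-10)
})

test_that("EMSC recovers constructed weights and corrects exactly", {
  ax <- default_axis(n = 400)
  p <- spectral_phantom_params()
  R <- new_spectrum(ax, class_signature("HT1197", p, ax), id = "ref")
  B <- new_spectrum(ax, cytoscreen:::glass_signature(p, ax), id = "glass")
  # identity: X0 = R
  r0 <- emsc_correct(R, R, B)
  expect_equal(r0$cr, 1, tolerance = 1e-10)
  expect_equal(r0$cb, 0, tolerance = 1e-10)
  expect_lt(max(abs(r0$cm)), 1e-10)
  expect_equal(r0$corrected$intensities, R$intensities, tolerance = 1e-8)
  # constructed: X0 = 2R + 3B + (0.5 P0 + 1.2 P1)
  P <- cytoscreen:::legendre_basis(as.numeric(ax), 5)
  x0 <- new_spectrum(ax, 2 * R$intensities + 3 * B$intensities +
                       0.5 * P[, 1] + 1.2 * P[, 2])
  fit <- emsc_correct(x0, R, B)
  expect_equal(fit$cr, 2, tolerance = 1e-8)
  expect_equal(fit$cb, 3, tolerance = 1e-8)
  expect_equal(fit$cm[1:2], c(0.5, 1.2), tolerance = 1e-8)
  expect_lt(max(abs(fit$cm[3:6])), 1e-8)
  expect_equal(fit$corrected$intensities, R$intensities, tolerance = 1e-8)
  expect_lt(fit$residual_norm, 1e-8)
  # normal-equations oracle on the same design matrix
  D <- cbind(R$intensities, B$intensities, P)
  beta <- solve(crossprod(D), crossprod(D, x0$intensities))
  expect_equal(unname(c(fit$cr, fit$cb, fit$cm)), drop(beta),
               tolerance = 1e-8)
  # degenerate inputs
  expect_error(emsc_correct(x0, R, R), "collinear")
  expect_error(emsc_correct(new_spectrum(ax, -2 * R$intensities), R, B),
               "cr")
  # exact scale equivariance
  x2 <- new_spectrum(ax, 5 * x0$intensities)
  fit2 <- emsc_correct(x2, R, B)
  expect_equal(fit2$cr, 5 * fit$cr, tolerance = 1e-8)
  expect_equal(fit2$corrected$intensities, fit$corrected$intensities,
               tolerance = 1e-7)
})

test_that("EMSC strips noise-free phantom background to the reference", {
  ax <- default_axis(n = 512)
  p <- spectral_phantom_params()
  R <- new_spectrum(ax, class_signature("RT112", p, ax))
  B <- new_spectrum(ax, cytoscreen:::glass_signature(p, ax))
  P <- cytoscreen:::legendre_basis(as.numeric(ax), 5)
  withr::with_seed(17, {
    for (k in 1:10) {
      cr <- runif(1, 0.5, 2)
      cb <- runif(1, 0.3, 3)
      cm <- runif(6, -20, 20)
      x0 <- new_spectrum(ax, cr * R$intensities + cb * B$intensities +
                           drop(P %*% cm))
      fit <- emsc_correct(x0, R, B)
      expect_equal(c(fit$cr, fit$cb), c(cr, cb), tolerance = 1e-8)
      expect_lt(fit$residual_norm, 1e-8)
      expect_lt(max(abs(fit$corrected$intensities - R$intensities)), 1e-8)
    }
  })
})

test_that("Savitzky-Golay reproduces polynomials and matches a sliding fit", {
  ax <- seq(600, 1800, length.out = 101)
  u <- seq(-2, 2, length.out = 101)
  cub <- 3 - u + 0.5 * u^2 - 2 * u^3
  sm <- savitzky_golay(new_spectrum(ax, cub), 7, 3)
  expect_lt(max(abs(sm$intensities - cub)), 1e-10)   # edges included
  expect_equal(savitzky_golay(rep(4, 50), 7, 3), rep(4, 50))
  # sliding local least-squares oracle (independent lm refit per window)
  withr::with_seed(13, x <- rnorm(80))
  got <- savitzky_golay(x, 7, 3)
  oracle <- vapply(seq_along(x), function(i) {
    idx <- max(1, i - 3):min(length(x), i + 3)
    unname(stats::lm(y ~ poly(t, 3, raw = TRUE),
                     data = data.frame(y = x[idx], t = idx - i))
           $coefficients[1])
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_error(savitzky_golay(x, 6, 3), "odd")
  expect_error(savitzky_golay(x, 3, 3), "exceed")
  expect_error(savitzky_golay(x[1:5], 7, 3), "shorter")
})

test_that("interior channels agree with the reference SG filter", {
  skip_if_not_installed("signal")
  withr::with_seed(14, x <- rnorm(120, 50, 5))
  mine <- savitzky_golay(x, 9, 3)
  ref <- signal::sgolayfilt(x, p = 3, n = 9)
  expect_equal(mine[5:116], ref[5:116], tolerance = 1e-10)
})

test_that("quality cull keeps r >= threshold and reports retention", {
  ax <- seq(600, 1800, length.out = 100)
  ref <- new_spectrum(ax, 50 + 30 * exp(-(ax - 1003)^2 / 200))
  m <- rbind(ref$intensities, ref$intensities * 1.3 + 2, -ref$intensities)
  rownames(m) <- c("a", "b", "neg")
  ss <- spectrum_set(ax, m)
  res <- quality_cull(ss, ref)
  expect_equal(attr(res$report, "retention"), 2 / 3)
  expect_false(res$report$retained[res$report$id == "neg"])
  expect_equal(n_spectra(res$spectra), 2)
  # all equal to the reference: retention 1
  all_ref <- spectrum_set(ax, rbind(ref$intensities, ref$intensities))
  expect_equal(attr(quality_cull(all_ref, ref)$report, "retention"), 1)
  # retention is monotone non-increasing in the noise level
  withr::with_seed(15, {
    retention <- vapply(c(0.5, 2, 8, 20), function(s) {
      noisy <- sweep(matrix(rnorm(30 * 100, 0, s), 30), 2,
                     ref$intensities, `+`)
      attr(quality_cull(spectrum_set(ax, noisy), ref)$report, "retention")
    }, numeric(1))
  })
  expect_true(all(diff(retention) <= 0))
})

test_that("a clean low-noise phantom survives the full pipeline unculled", {
  ss <- generate_spectrum_set(30, seed = 19)
  glass <- generate_glass_set(10, seed = 20)
  rep <- run_full_pipeline(ss, glass, cfg = run_config(seed = 19, folds = 5,
                                                       ref_k = 30))
  expect_equal(rep$retention, 1.0)
  expect_equal(n_spectra(rep$processed), 60)
})
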