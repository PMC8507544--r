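test_that("variance metric matches its definition", {
  expect_equal(variance_metric(matrix(7, 5, 5)), 0)
  expect_equal(variance_metric(matrix(c(0, 2), 1, 2)), 1.0)
  withr::with_seed(1, img <- matrix(runif(400, 1, 10), 20, 20))
  mu <- mean(img)
  oracle <- sum((img - mu)^2) / length(img) / mu     # two-pass population
  expect_equal(variance_metric(img), oracle, tolerance = 1e-10)
  expect_equal(variance_metric(img, "cv_squared"), oracle / mu,
               tolerance = 1e-10)
  expect_error(variance_metric(matrix(0, 2, 2)), "mean")
})

test_that("autofocus finds the bright-spot peak and nearest interior minimum", {
  z <- seq(-10, 30, 2)
  m <- exp(-(z - 14)^2 / 50) + 0.3 * z^2 / (z^2 + 25)
  fr <- autofocus(variance_profile(z, m))
  expect_equal(fr$z_bright_spot, 14)
  expect_equal(fr$z_focus, 0)
  # orientation invariance: reversed scan gives the same physical planes
  fr_rev <- autofocus(variance_profile(rev(z), rev(m)))
  expect_equal(fr_rev$z_bright_spot, fr$z_bright_spot)
  expect_equal(fr_rev$z_focus, fr$z_focus)
  # ties between equidistant minima break toward z = 0
  zt <- -3:3
  mt <- c(5, 1, 2, 9, 2, 1, 5)
  expect_equal(autofocus(variance_profile(zt, mt))$z_focus, -2)
  expect_error(autofocus(variance_profile(1:10, 1:10)), "boundary")
  expect_error(autofocus(variance_profile(1:4, c(1, 3, 2, 1))), "5 z samples")
})

test_that("autofocus recovers the planted plane from a rendered stack", {
  ph <- generate_slide(15, seed = 6)
  zs <- seq(-10, 30, 2)
  m <- vapply(zs, function(z) {
    variance_metric(render_image(ph, stage_xy = c(110, 110), z = z,
                                 seed = 900 + z))
  }, numeric(1))
  fr <- autofocus(variance_profile(zs, m))
  expect_lte(abs(fr$z_bright_spot - 14), 2)
})

test_that("stitching recovers crop offsets and falls back gracefully", {
  ph <- generate_slide(30, seed = 8)
  big <- render_image(ph, stage_xy = c(110, 110), z = 14, fov = c(300, 300),
                      pixel_size = 0.5, seed = 4)
  # two tiles cut from one field with ~10% overlap; truth offset (0, 115)
  a <- big$pixels[1:128, 1:128]
  b <- big$pixels[1:128, 116:243]
  # stage positions deliberately off by ~2 px from the true offset
  t1 <- image_tile(a, stage_xy = c(110, 110), z = 14, pixel_size = 0.5)
  t2 <- image_tile(b, stage_xy = c(110 + 56.5, 110), z = 14,
                   pixel_size = 0.5)
  st <- stitch_grid(list(t1, t2), nominal_overlap = 0.1)
  rel <- c(st$offsets$row_off[2] - st$offsets$row_off[1],
           st$offsets$col_off[2] - st$offsets$col_off[1])
  expect_lt(max(abs(rel - c(0, 115))), 0.5)
  expect_true(st$offsets$refined[2])
  # single tile: identity
  st1 <- stitch_grid(list(t1))
  expect_equal(st1$mosaic, a)
  expect_equal(unlist(st1$offsets[1, c("row_off", "col_off")]),
               c(row_off = 0, col_off = 0))
  # constant tiles: nominal offsets used, no failure
  c1 <- image_tile(matrix(5, 64, 64), c(0, 0), 0, 0.5)
  c2 <- image_tile(matrix(5, 64, 64), c(28.8, 0), 0, 0.5)
  stc <- stitch_grid(list(c1, c2))
  expect_false(any(stc$offsets$refined))
  expect_equal(stc$offsets$col_off[2] - stc$offsets$col_off[1], 57.6)
  # non-grid layouts are rejected
  c3 <- image_tile(matrix(5, 64, 64), c(13, 17), 0, 0.5)
  expect_error(stitch_grid(list(c1, c2, c3)), "grid")
})

test_that("bright-spot detection finds spots and honours its parameters", {
  mk_spot <- function(img, r, c, amp = 100, sd = 2) {
    for (dr in -6:6) for (dc in -6:6) {
      img[r + dr, c + dc] <- img[r + dr, c + dc] +
        amp * exp(-(dr^2 + dc^2) / (2 * sd^2))
    }
    img
  }
  img <- matrix(10, 96, 96)
  img <- mk_spot(img, 33, 49)
  cs <- detect_bright_spots(img, sigma = 2, min_distance = 5)
  expect_equal(nrow(cs), 1)
  expect_lt(abs(cs$row - 32) + abs(cs$col - 48), 1.5)  # 0-based
  # constant image: empty set
  expect_equal(nrow(detect_bright_spots(matrix(3, 50, 50))), 0)
  # 3x3 grid of 9 spots
  img9 <- matrix(10, 120, 120)
  truth <- expand.grid(r = c(25, 60, 95), c = c(25, 60, 95))
  for (i in seq_len(9)) img9 <- mk_spot(img9, truth$r[i], truth$c[i])
  cs9 <- detect_bright_spots(img9, sigma = 2, min_distance = 8)
  expect_equal(nrow(cs9), 9)
  d <- sapply(seq_len(9), function(i) {
    min(sqrt((cs9$row + 1 - truth$r)^2 + (cs9$col + 1 - truth$c)^2))
  })
  expect_lt(max(d), 1.01)
  # candidate count is monotone non-increasing in prominence / min_distance
  ph <- generate_slide(30, seed = 12)
  mos <- render_image(ph, stage_xy = c(110, 110), z = 14, fov = c(300, 300),
                      seed = 5)$pixels
  n_prom <- vapply(c(0.1, 0.3, 0.5, 0.7), function(pr) {
    nrow(detect_bright_spots(mos, prominence = pr))
  }, numeric(1))
  expect_true(all(diff(n_prom) <= 0))
  n_dist <- vapply(c(4, 8, 16, 32), function(md) {
    nrow(detect_bright_spots(mos, min_distance = md))
  }, numeric(1))
  expect_true(all(diff(n_dist) <= 0))
})

test_that("isolation filtering keeps the most isolated candidates", {
  cs <- tibble::tibble(row = c(0, 1, 100), col = c(0, 0, 100),
                       score = c(5, 4, 3))
  cs$isolation <- c(1, 1, sqrt(2) * 99.5)
  class(cs) <- c("candidate_set", class(tibble::tibble()))
  kept <- select_isolated(cs, 1)
  expect_equal(c(kept$row, kept$col), c(100, 100))
  expect_equal(nrow(select_isolated(cs, 3)), 3)
  expect_equal(nrow(select_isolated(cs, 99)), 3)
  # oracle: survivors' nearest-neighbour distances dominate the discarded
  withr::with_seed(3, {
    big <- tibble::tibble(row = runif(200, 0, 500), col = runif(200, 0, 500),
                          score = runif(200))
  })
  big$isolation <- 0
  class(big) <- c("candidate_set", class(tibble::tibble()))
  d <- as.matrix(dist(cbind(big$row, big$col)))
  diag(d) <- Inf
  iso_all <- apply(d, 1, min)
  kept50 <- select_isolated(big, 50)
  kept_key <- paste(kept50$row, kept50$col)
  all_key <- paste(big$row, big$col)
  kept_idx <- match(kept_key, all_key)
  expect_gte(min(iso_all[kept_idx]), max(iso_all[-kept_idx]) - 1e-9)
})

test_that("route ordering is greedy nearest-neighbour and shortens travel", {
  pts <- tibble::tibble(x_um = c(20, 0, 30, 10), y_um = 0)
  tl <- order_route(pts, start = c(0, 0))
  expect_equal(tl$x_um, c(0, 10, 20, 30))
  expect_equal(tl$order, 1:4)
  one <- order_route(tibble::tibble(x_um = 5, y_um = 5), c(0, 0))
  expect_equal(nrow(one), 1)
  tour_len <- function(df, start) {
    xs <- c(start[1], df$x_um); ys <- c(start[2], df$y_um)
    sum(sqrt(diff(xs)^2 + diff(ys)^2))
  }
  withr::with_seed(11, {
    pts100 <- tibble::tibble(x_um = runif(100, 0, 200),
                             y_um = runif(100, 0, 200))
  })
  greedy <- tour_len(order_route(pts100, c(0, 0)), c(0, 0))
  expect_lte(greedy, tour_len(pts100, c(0, 0)))
  # exhaustive-permutation oracle at n <= 8: greedy is never shorter than
  # the optimal tour
  withr::with_seed(12, {
    pts7 <- tibble::tibble(x_um = runif(7, 0, 50), y_um = runif(7, 0, 50))
  })
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- min(vapply(perms(1:7), function(p) {
    tour_len(pts7[p, ], c(0, 0))
  }, numeric(1)))
  g7 <- tour_len(order_route(pts7, c(0, 0)), c(0, 0))
  expect_gte(g7 + 1e-9, best)
})

test_that("pixel-to-stage affine fit recovers synthetic maps", {
  px <- cbind(c(0, 0, 10, 10, 3), c(0, 10, 0, 10, 7))
  ident <- fit_pixel_to_stage(px, px)
  expect_equal(ident$A, diag(2), tolerance = 1e-12)
  expect_equal(ident$t, c(0, 0), tolerance = 1e-12)
  expect_lt(ident$rms_residual, 1e-12)
  # scale 0.1613 um/px with a y-flip and offset, 10 random points
  withr::with_seed(21, px10 <- matrix(runif(20, 0, 2000), 10, 2))
  A_true <- matrix(c(0, 0.1613, -0.1613, 0), 2, 2)   # x from col, y from -row
  t_true <- c(500, -200)
  stage <- t(A_true %*% t(px10)) + matrix(t_true, 10, 2, byrow = TRUE)
  fit <- fit_pixel_to_stage(px10, stage)
  expect_lt(max(abs(fit$A - A_true)), 1e-9)
  expect_lt(max(abs(fit$t - t_true)), 1e-9)
  back <- pixel_to_stage(fit, px10)
  expect_lt(max(abs(cbind(back$x_um, back$y_um) - stage)), 1e-9)
  expect_error(fit_pixel_to_stage(cbind(1:3, 1:3), cbind(1:3, 1:3)),
               "collinear")
  expect_error(fit_pixel_to_stage(px10[1:2, ], stage[1:2, ]), "3 correspond")
})

test_that("laser offset translates uniformly and inverts exactly", {
  tl <- order_route(tibble::tibble(x_um = c(10, 20), y_um = c(10, 0)),
                    c(0, 0))
  same <- apply_laser_offset(tl, c(0, 0))
  expect_equal(same$x_um, tl$x_um)
  shifted <- apply_laser_offset(tl, c(3, -2))
  expect_equal(shifted$x_um, tl$x_um + 3)
  expect_equal(shifted$y_um, tl$y_um - 2)
  expect_equal(shifted$order, tl$order)
  back <- apply_laser_offset(shifted, c(-3, 2))
  expect_equal(back, tl)
})
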