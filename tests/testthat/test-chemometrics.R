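test_that("marginal relevance matches the double-loop oracle", {
  withr::with_seed(1, {
    X <- matrix(rnorm(50 * 200), 50, 200)
    y <- rep(c("A", "B"), each = 25)
  })
  got <- marginal_relevance(X, y)$score
  # explicit double-loop between/within sum-of-squares oracle
  oracle <- vapply(seq_len(ncol(X)), function(j) {
    xb <- mean(X[, j])
    B <- W <- 0
    for (cl in unique(y)) {
      xk <- X[y == cl, j]
      B <- B + length(xk) * (mean(xk) - xb)^2
      W <- W + sum((xk - mean(xk))^2)
    }
    B / W
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("marginal relevance handles planted effects and edge cases", {
  pm <- planted_matrix(n_per_class = 40, p = 60, channels = 7, delta = 4)
  sc <- marginal_relevance(pm$X, pm$y)
  expect_equal(which.max(sc$score), 7)
  # identical class distributions per channel: all zeros
  X0 <- rbind(diag(4), diag(4))
  expect_equal(marginal_relevance(X0, rep(c("A", "B"), each = 4))$score,
               rep(0, 4))
  # W = 0 with B > 0 gives the +Inf sentinel; B = W = 0 gives 0
  Xd <- cbind(rep(c(0, 1), each = 3), rep(2, 6))
  scd <- marginal_relevance(Xd, rep(c("A", "B"), each = 3))$score
  expect_equal(scd, c(Inf, 0))
  expect_error(marginal_relevance(Xd, c("A", "A", "A", "A", "A", "B")),
               "at least 2 samples")
  # invariance to per-channel shifts; scale invariance of the ratio
  shifted <- sweep(pm$X, 2, seq_len(ncol(pm$X)), `+`)
  expect_equal(marginal_relevance(shifted, pm$y)$score, sc$score,
               tolerance = 1e-9)
  expect_equal(marginal_relevance(3 * pm$X, pm$y)$score, sc$score,
               tolerance = 1e-9)
})

test_that("region-wise channel selection matches a block argmax oracle", {
  # ten unit impulses, one per region of 10 channels
  s <- rep(0, 100)
  hits <- c(3, 17, 25, 38, 44, 57, 62, 78, 85, 99)
  s[hits] <- 1
  expect_equal(select_mr_channels(s, 10), hits)
  # constant scores: first channel of each region (tie rule)
  expect_equal(select_mr_channels(rep(1, 100), 10),
               seq(1, 91, by = 10))
  # random scores against a brute-force per-block scan
  withr::with_seed(2, sr <- runif(103))
  got <- select_mr_channels(sr, 10)
  bounds <- round(seq(0, 103, length.out = 11))
  oracle <- vapply(1:10, function(b) {
    idx <- (bounds[b] + 1):bounds[b + 1]
    idx[which.max(sr[idx])]
  }, integer(1))
  expect_equal(got, oracle)
  expect_error(select_mr_channels(1:5, 10), "fewer channels")
})

test_that("stratified folds balance classes and reproduce under a seed", {
  y <- rep(c("A", "B"), each = 50)
  f <- stratified_folds(y, 10, seed = 4)
  tab <- table(f, y)
  expect_true(all(tab == 5))
  expect_identical(stratified_folds(y, 10, 4), f)
  expect_false(identical(stratified_folds(y, 10, 5), f))
  # 53 vs 47
  y2 <- rep(c("A", "B"), c(53, 47))
  f2 <- stratified_folds(y2, 10, 1)
  tab2 <- table(f2, y2)
  expect_true(all(tab2[, "A"] %in% 5:6))
  expect_true(all(tab2[, "B"] %in% 4:5))
  expect_equal(colSums(tab2), c(A = 53, B = 47))
  expect_error(stratified_folds(rep(c("A", "B"), c(5, 50)), 10), "smaller")
})

test_that("only the eleven studied pipelines are constructible", {
  specs <- default_pipeline_specs()
  expect_length(specs, 11)
  expect_setequal(names(specs),
                  c("SVM", "RF", "PLS", "PCA_LDA", "PCA_QDA", "PCA_kNN",
                    "MR_LDA", "MR_QDA", "MR_kNN", "MR_RF", "MR_SVM"))
  expect_error(pipeline_spec("pca", "rf"), "not one of the 11")
  expect_error(pipeline_spec("none", "lda"), "not one of the 11")
  expect_error(pipeline_spec("pca", "pls"), "not one of the 11")
})

test_that("classification metrics follow their definitions", {
  cm <- matrix(c(50, 0, 0, 50), 2, byrow = TRUE)
  expect_equal(unname(classification_metrics(cm)), c(1, 1, 1))
  cm2 <- matrix(c(45, 5, 10, 40), 2, byrow = TRUE,
                dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- classification_metrics(cm2, positive = "pos")
  expect_equal(unname(m), c(0.85, 0.90, 0.80))
  # swapping the positive class swaps sensitivity and specificity
  withr::with_seed(6, {
    for (k in 1:10) {
      cmr <- matrix(rpois(4, 20) + 1, 2,
                    dimnames = list(c("a", "b"), c("a", "b")))
      ma <- classification_metrics(cmr, "a")
      mb <- classification_metrics(cmr, "b")
      expect_equal(ma[["accuracy"]], mb[["accuracy"]])
      expect_equal(ma[["sensitivity"]], mb[["specificity"]])
      expect_equal(ma[["specificity"]], mb[["sensitivity"]])
    }
  })
  expect_error(classification_metrics(matrix(c(0, 0, 3, 4), 2,
                                             byrow = TRUE)), "margin")
})

test_that("PLS regression separates coded classes and caps components", {
  pm <- planted_matrix(n_per_class = 30, p = 25, channels = c(3, 11),
                       delta = 5, seed = 7)
  code <- ifelse(pm$y == "A", 1, -1)
  fit <- cytoscreen:::pls_fit(pm$X, code, 15)
  pred <- cytoscreen:::pls_predict(fit, pm$X)
  expect_true(all(sign(pred) == code))
  # component count is capped by the rank of a tiny training set
  rows <- c(1:4, 31:34)
  small <- cytoscreen:::pls_fit(pm$X[rows, ], code[rows], 15)
  expect_true(all(is.finite(cytoscreen:::pls_predict(small, pm$X))))
})

test_that("three-PC reduction is Eckart-Young optimal on small matrices", {
  withr::with_seed(8, X <- matrix(rnorm(40 * 12), 40, 12) %*%
                     diag(c(8, 5, 3, rep(0.4, 9))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  V <- svd(Xc, nv = 3)$v
  err_svd <- sum((Xc - Xc %*% V %*% t(V))^2)
  withr::with_seed(9, {
    for (k in 1:20) {
      Q <- qr.Q(qr(matrix(rnorm(12 * 3), 12, 3)))
      expect_gte(sum((Xc - Xc %*% Q %*% t(Q))^2), err_svd - 1e-9)
    }
  })
})

test_that("well-separated classes are classified perfectly by every spec", {
  pm <- planted_matrix(n_per_class = 100, p = 30,
                       channels = c(5, 12, 25), delta = 10, seed = 10)
  cv <- crossvalidate(pm$X, pm$y, k = 10, seed = 11, positive = "A")
  expect_equal(nrow(cv$metrics), 11)
  expect_true(all(cv$metrics$accuracy == 1))
  expect_true(all(cv$metrics$sensitivity == 1))
  expect_true(all(cv$metrics$specificity == 1))
  # report invariants: folds partition the data, stratified within class
  expect_true(all(table(cv$folds, pm$y) == 10))
  expect_equal(sort(unique(cv$predictions$row)), 1:200)
})

test_that("label-shuffled data scores at chance for every spec", {
  withr::with_seed(12, {
    X <- matrix(rnorm(200 * 30), 200, 30)
    y <- sample(rep(c("A", "B"), each = 100))
  })
  cv <- crossvalidate(X, y, k = 10, seed = 13, positive = "A")
  band <- qnorm(0.995) * sqrt(0.25 / 200)
  expect_true(all(abs(cv$metrics$accuracy - 0.5) <= band))
})

test_that("reducers never see test rows (leakage guard)", {
  pm <- planted_matrix(n_per_class = 30, p = 20, channels = 4, delta = 6,
                       seed = 14)
  specs <- default_pipeline_specs()[c("PCA_LDA", "MR_LDA")]
  cv1 <- crossvalidate(pm$X, pm$y, specs, k = 5, seed = 15, positive = "A")
  # perturb one test row of fold 1; all other predictions must be unchanged
  row_pert <- which(cv1$folds == 1)[1]
  X2 <- pm$X
  X2[row_pert, ] <- X2[row_pert, sample(20)]
  cv2 <- crossvalidate(X2, pm$y, specs, k = 5, seed = 15, positive = "A")
  p1 <- cv1$predictions[cv1$predictions$row != row_pert, ]
  p2 <- cv2$predictions[cv2$predictions$row != row_pert, ]
  expect_identical(p1$pred, p2$pred)
})

test_that("degenerate QDA folds are excluded with a warning, not silently", {
  # constant-within-class features make the QDA covariance singular
  X <- cbind(rep(c(1, 2), each = 20), rep(c(3, 4), each = 20))
  y <- rep(c("A", "B"), each = 20)
  specs <- list(pipeline_spec("pca", "qda"))
  expect_warning(cv <- crossvalidate(X, y, specs, k = 5, seed = 16,
                                     positive = "A"),
                 "excluded")
  expect_gt(nrow(cv$errors), 0)
})

test_that("cv_report exposes tidy, glance and per-fold plots", {
  pm <- planted_matrix(n_per_class = 25, p = 15, channels = 2, delta = 6,
                       seed = 17)
  cv <- crossvalidate(pm$X, pm$y,
                      list(pipeline_spec("none", "pls")), k = 5, seed = 18,
                      positive = "A")
  td <- tidy(cv)
  expect_named(td, c("spec", "accuracy", "sensitivity", "specificity"))
  gl <- glance(cv)
  expect_equal(gl$n, 50)
  expect_equal(gl$k, 5)
  expect_s3_class(autoplot(cv), "ggplot")
})
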