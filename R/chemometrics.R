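# Statistical layer: marginal-relevance wavelength scoring, PCA / MR feature
# reduction fitted per training split, eleven classifier configurations,
# stratified 10-fold cross-validation and pooled confusion-matrix metrics.
# MR, the stratification, the CV harness and the metrics are implemented
# here; LDA/QDA, kNN, RF and SVM engines are MASS, class, ranger and kernlab.

#' Marginal-relevance scores
#'
#' For every channel independently, the ratio of the between-class to the
#' within-class sum of squares:
#' `B_j = sum_k n_k (xbar_kj - xbar_j)^2`,
#' `W_j = sum_k sum_{i in k} (x_ij - xbar_kj)^2`, score `B_j / W_j`.
#' A channel with `W_j = 0` but `B_j > 0` scores `Inf`; `0/0` scores 0.
#'
#' @param X Numeric n x p matrix (rows samples, columns channels).
#' @param y Class labels (>= 2 classes, each with >= 2 samples).
#' @param axis Optional wavenumber axis for labelling.
#' @return A tibble of class `mr_scores`: `channel`, `score` (and
#'   `wavenumber` when `axis` is supplied).
#' @export
marginal_relevance <- function(X, y, axis = NULL) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes", call. = FALSE)
  cnt <- table(y)
  if (any(cnt < 2)) {
    stop("every class needs at least 2 samples (violated by: ",
         paste(names(cnt)[cnt < 2], collapse = ", "), ")", call. = FALSE)
  }
  grand <- colMeans(X)
  B <- numeric(ncol(X))
  W <- numeric(ncol(X))
  for (cl in levels(y)) {
    Xk <- X[y == cl, , drop = FALSE]
    mk <- colMeans(Xk)
    B <- B + nrow(Xk) * (mk - grand)^2
    W <- W + colSums(sweep(Xk, 2, mk)^2)
  }
  score <- ifelse(W > 0, B / W, ifelse(B > 0, Inf, 0))
  out <- tibble::tibble(channel = seq_len(ncol(X)), score = score)
  if (!is.null(axis)) out$wavenumber <- as.numeric(axis)
  class(out) <- c("mr_scores", class(tibble::tibble()))
  out
}

#' Pick the top-scoring channel from each of n contiguous regions
#'
#' The channel axis is partitioned into `n_regions` contiguous blocks of
#' equal width (within one channel); from each block the argmax-score channel
#' is returned (ties to the lowest index). Neighbouring wavelengths carry
#' similar MR scores, so spreading the selection over regions avoids picking
#' one band's shoulder channels repeatedly.
#'
#' @param scores An `mr_scores` tibble or numeric score vector.
#' @param n_regions Number of regions (default 10).
#' @return Integer vector of selected channel indices, one per region.
#' @export
select_mr_channels <- function(scores, n_regions = 10) {
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  p <- length(s)
  if (p < n_regions) stop("fewer channels than regions", call. = FALSE)
  bounds <- round(seq(0, p, length.out = n_regions + 1))
  vapply(seq_len(n_regions), function(b) {
    idx <- (bounds[b] + 1):bounds[b + 1]
    idx[which.max(s[idx])]
  }, integer(1))
}

#' Stratified k-fold assignment
#'
#' Within each class a seeded random permutation is dealt round-robin into
#' the k folds, so per-fold class counts differ by at most one sample.
#'
#' @param y Class labels; every class must have at least `k` samples.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k), one per sample.
#' @export
stratified_folds <- function(y, k = 10, seed = 1) {
  y <- as.factor(y)
  cnt <- table(y)
  if (any(cnt < k)) {
    stop("class smaller than k folds: ",
         paste(names(cnt)[cnt < k], collapse = ", "), call. = FALSE)
  }
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      perm <- sample(idx)
      folds[perm] <- (seq_along(perm) - 1) %% k + 1
    }
  })
  folds
}

#' Classifier pipeline specification
#'
#' Only the eleven studied reducer/classifier combinations are
#' constructible: PCA (3 components) feeding LDA, QDA or kNN; MR-selected
#' wavelengths (10 regions) feeding LDA, QDA, kNN, RF or SVM; and RF, SVM,
#' PLS on all wavelengths.
#'
#' @param reducer `"none"`, `"pca"` or `"mr"`.
#' @param classifier `"lda"`, `"qda"`, `"knn"`, `"rf"`, `"svm"` or `"pls"`.
#' @param pca_ncomp Principal components kept (3).
#' @param mr_regions MR regions / channels kept (10).
#' @param knn_k Neighbours for kNN (5).
#' @param rf_trees Random-forest trees (500); `mtry` is the rounded-down
#'   square root of the feature count.
#' @param pls_lv PLS latent variables (15, deliberately large and untuned).
#' @return A `pipeline_spec` list with a display `name` such as `"MR_kNN"`.
#' @export
pipeline_spec <- function(reducer = c("none", "pca", "mr"),
                          classifier = c("lda", "qda", "knn", "rf", "svm",
                                         "pls"),
                          pca_ncomp = 3, mr_regions = 10, knn_k = 5,
                          rf_trees = 500, pls_lv = 15) {
  reducer <- match.arg(reducer)
  classifier <- match.arg(classifier)
  allowed <- list(pca = c("lda", "qda", "knn"),
                  mr = c("lda", "qda", "knn", "rf", "svm"),
                  none = c("rf", "svm", "pls"))
  if (!classifier %in% allowed[[reducer]]) {
    stop("combination ", reducer, " + ", classifier,
         " is not one of the 11 studied configurations", call. = FALSE)
  }
  disp <- c(lda = "LDA", qda = "QDA", knn = "kNN", rf = "RF", svm = "SVM",
            pls = "PLS")[classifier]
  name <- switch(reducer, none = disp, pca = paste0("PCA_", disp),
                 mr = paste0("MR_", disp))
  structure(list(reducer = reducer, classifier = classifier,
                 pca_ncomp = pca_ncomp, mr_regions = mr_regions,
                 knn_k = knn_k, rf_trees = rf_trees, pls_lv = pls_lv,
                 name = unname(name)),
            class = "pipeline_spec")
}

#' The eleven studied pipeline configurations
#'
#' @return Named list of [pipeline_spec()]s in reporting order.
#' @export
default_pipeline_specs <- function() {
  combos <- list(c("none", "svm"), c("none", "rf"), c("none", "pls"),
                 c("pca", "lda"), c("pca", "qda"), c("pca", "knn"),
                 c("mr", "lda"), c("mr", "qda"), c("mr", "knn"),
                 c("mr", "rf"), c("mr", "svm"))
  specs <- lapply(combos, function(cc) pipeline_spec(cc[1], cc[2]))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# --- internal engines ------------------------------------------------------

# Gaussian-kernel bandwidth: midrange of the 0.1 / 0.9 quantiles of
# 1 / (2 ||x - x'||^2) over a seeded subsample of pairs (sigest-style).
rbf_sigma <- function(X, seed = 1, max_rows = 200) {
  withr::with_seed(seed, {
    idx <- if (nrow(X) > max_rows) sample.int(nrow(X), max_rows)
           else seq_len(nrow(X))
    d2 <- as.numeric(stats::dist(X[idx, , drop = FALSE]))^2
    d2 <- d2[d2 > 0]
    if (length(d2) == 0) return(1)
    q <- stats::quantile(d2, c(0.9, 0.1), names = FALSE)
    mean(1 / (2 * q))
  })
}

pls_fit <- function(X, y01, ncomp) {
  X <- as.matrix(X)
  xm <- colMeans(X)
  ym <- mean(y01)
  Xc <- sweep(X, 2, xm)
  yc <- y01 - ym
  ncomp <- min(ncomp, ncol(X), nrow(X) - 1)
  W <- P <- matrix(0, ncol(X), ncomp)
  q <- numeric(ncomp)
  used <- 0
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    p <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, p)
    yc <- yc - t * qa
    W[, a] <- w
    P[, a] <- p
    q[a] <- qa
    used <- a
  }
  if (used == 0) stop("PLS: no usable latent variable", call. = FALSE)
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  q <- q[seq_len(used)]
  B <- W %*% solve(crossprod(P, W), q)
  list(B = B, xm = xm, ym = ym)
}

pls_predict <- function(fit, X) {
  drop(sweep(as.matrix(X), 2, fit$xm) %*% fit$B) + fit$ym
}

fit_reducer <- function(spec, Xtr, ytr) {
  switch(spec$reducer,
    none = list(transform = function(X) X),
    pca = {
      mu <- colMeans(Xtr)
      nv <- min(spec$pca_ncomp, ncol(Xtr), nrow(Xtr) - 1)
      V <- svd(sweep(Xtr, 2, mu), nu = 0, nv = nv)$v
      list(transform = function(X) sweep(as.matrix(X), 2, mu) %*% V)
    },
    mr = {
      idx <- select_mr_channels(marginal_relevance(Xtr, ytr),
                                n_regions = spec$mr_regions)
      list(transform = function(X) as.matrix(X)[, idx, drop = FALSE],
           channels = idx)
    })
}

fit_and_predict <- function(spec, Ztr, ytr, Zte, seed) {
  lv <- levels(ytr)
  switch(spec$classifier,
    lda = {
      fit <- MASS::lda(Ztr, grouping = ytr)
      as.character(stats::predict(fit, Zte)$class)
    },
    qda = {
      fit <- MASS::qda(Ztr, grouping = ytr)
      as.character(stats::predict(fit, Zte)$class)
    },
    knn = withr::with_seed(seed, {
      as.character(class::knn(Ztr, Zte, ytr, k = spec$knn_k))
    }),
    rf = {
      df <- as.data.frame(Ztr)
      names(df) <- paste0("f", seq_len(ncol(Ztr)))
      df$.y <- ytr
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = spec$rf_trees,
        mtry = max(1, floor(sqrt(ncol(Ztr)))),
        seed = seed, num.threads = 1)
      te <- as.data.frame(Zte)
      names(te) <- paste0("f", seq_len(ncol(Zte)))
      as.character(stats::predict(fit, te, num.threads = 1)$predictions)
    },
    svm = {
      sig <- rbf_sigma(Ztr, seed)
      fit <- withr::with_seed(seed, kernlab::ksvm(
        as.matrix(Ztr), ytr, kernel = "rbfdot",
        kpar = list(sigma = sig), C = 1, scaled = FALSE))
      as.character(kernlab::predict(fit, as.matrix(Zte)))
    },
    pls = {
      code <- ifelse(ytr == lv[1], 1, -1)
      fit <- pls_fit(Ztr, code, spec$pls_lv)
      ifelse(pls_predict(fit, Zte) >= 0, lv[1], lv[2])
    })
}

#' Stratified cross-validation of classifier pipelines
#'
#' For every fold, each pipeline's reducer (PCA or MR) is fitted on the
#' training rows only and applied to the test rows, the classifier is fitted
#' with the fixed hyperparameters of the spec, and test predictions are
#' recorded; confusion matrices are pooled over folds. All specs share the
#' same fold assignment. A fold whose QDA covariance is degenerate is
#' recorded as an error for that spec, excluded, and reported with a warning
#' rather than failing silently.
#'
#' @param X Numeric n x p feature matrix (spectra as rows).
#' @param y Binary class labels.
#' @param specs List of [pipeline_spec()]s (default: all eleven).
#' @param k Number of folds.
#' @param seed Seed for folding and for the stochastic engines.
#' @param positive Positive class for sensitivity/specificity; defaults to
#'   `"HT1197"` when present (the high-grade line), else the first level.
#' @return A `cv_report`: list with `predictions` (tibble `row, fold, spec,
#'   truth, pred`), `metrics` (tibble `spec, accuracy, sensitivity,
#'   specificity`), `fold_metrics`, `confusion` (named list of 2x2 tables),
#'   `folds`, `errors`, `positive`, `seed`.
#' @export
crossvalidate <- function(X, y, specs = default_pipeline_specs(), k = 10,
                          seed = 1, positive = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite", call. = FALSE)
  y <- as.factor(as.character(y))
  if (nlevels(y) != 2) stop("binary labels required", call. = FALSE)
  if (is.null(positive)) {
    positive <- if ("HT1197" %in% levels(y)) "HT1197" else levels(y)[1]
  }
  if (inherits(specs, "pipeline_spec")) specs <- list(specs)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, `[[`, character(1), "name")
  }
  folds <- stratified_folds(y, k, seed)
  preds <- list()
  errors <- list()
  for (f in seq_len(k)) {
    tr <- folds != f
    te <- !tr
    for (sn in names(specs)) {
      spec <- specs[[sn]]
      sd_f <- derive_seed(seed, 1000 * f + match(sn, names(specs)))
      res <- tryCatch({
        red <- fit_reducer(spec, X[tr, , drop = FALSE], y[tr])
        Ztr <- red$transform(X[tr, , drop = FALSE])
        Zte <- red$transform(X[te, , drop = FALSE])
        fit_and_predict(spec, Ztr, y[tr], Zte, sd_f)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[length(errors) + 1]] <- tibble::tibble(
          spec = sn, fold = f, message = conditionMessage(res))
      } else {
        preds[[length(preds) + 1]] <- tibble::tibble(
          row = which(te), fold = f, spec = sn,
          truth = as.character(y[te]), pred = res)
      }
    }
  }
  predictions <- if (length(preds)) dplyr::bind_rows(preds) else
    tibble::tibble(row = integer(0), fold = integer(0), spec = character(0),
                   truth = character(0), pred = character(0))
  errors <- if (length(errors)) dplyr::bind_rows(errors) else
    tibble::tibble(spec = character(0), fold = integer(0),
                   message = character(0))
  if (nrow(errors) > 0) {
    warning(nrow(errors), " fold/spec fits failed and were excluded (",
            paste(unique(errors$spec), collapse = ", "), ")", call. = FALSE)
  }
  lv <- c(positive, setdiff(levels(y), positive))
  confusion <- lapply(split(predictions, predictions$spec), function(d) {
    table(factor(d$truth, lv), factor(d$pred, lv), dnn = c("truth", "pred"))
  })
  metrics <- dplyr::bind_rows(
    tibble::tibble(spec = character(0), accuracy = numeric(0),
                   sensitivity = numeric(0), specificity = numeric(0)),
    dplyr::bind_rows(lapply(names(confusion), function(sn) {
      m <- classification_metrics(confusion[[sn]], positive)
      tibble::tibble(spec = sn, accuracy = m[1], sensitivity = m[2],
                     specificity = m[3])
    })))
  metrics <- metrics[match(intersect(names(specs), metrics$spec),
                           metrics$spec), ]
  fold_metrics <- predictions |>
    dplyr::group_by(.data$spec, .data$fold) |>
    dplyr::summarise(accuracy = mean(.data$truth == .data$pred),
                     .groups = "drop")
  structure(list(predictions = predictions, metrics = metrics,
                 fold_metrics = fold_metrics, confusion = confusion,
                 folds = folds, errors = errors, positive = positive,
                 seed = seed),
            class = "cv_report")
}

#' Accuracy, sensitivity and specificity from a 2x2 confusion matrix
#'
#' Sensitivity is the true-positive rate of the designated positive
#' (high-grade) class; specificity the true-negative rate of the other.
#'
#' @param confusion 2x2 count matrix or table, rows truth, columns
#'   prediction. With dimnames, `positive` selects the positive row/column;
#'   without, the first row/column is taken as positive.
#' @param positive Positive class label.
#' @return Named numeric vector `accuracy, sensitivity, specificity`.
#' @export
classification_metrics <- function(confusion, positive = NULL) {
  cm <- as.matrix(unclass(confusion))
  stopifnot(all(dim(cm) == 2), all(cm >= 0))
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  if (!is.null(dimnames(cm)[[1]]) && !is.null(positive)) {
    i <- match(positive, rownames(cm))
    if (is.na(i)) stop("positive class not in confusion matrix",
                       call. = FALSE)
    ord <- c(i, setdiff(1:2, i))
    cm <- cm[ord, ord]
  }
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  if (tp + fn == 0 || tn + fp == 0) {
    stop("undefined metric: a truth margin is empty", call. = FALSE)
  }
  c(accuracy = (tp + tn) / sum(cm),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", length(unique(x$predictions$spec)), " pipelines, ",
      max(x$folds), "-fold stratified CV, positive class '", x$positive,
      "'\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the pooled per-pipeline metrics of a CV report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble `spec, accuracy, sensitivity, specificity`.
#' @export
tidy.cv_report <- function(x, ...) x$metrics

#' One-row summary of a CV report
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with sample count, fold count, pipeline count, and the
#'   best pipeline with its accuracy.
#' @export
glance.cv_report <- function(x, ...) {
  best <- x$metrics[which.max(x$metrics$accuracy), ]
  tibble::tibble(n = length(x$folds), k = max(x$folds),
                 n_specs = nrow(x$metrics), best_spec = best$spec,
                 best_accuracy = best$accuracy,
                 n_errors = nrow(x$errors))
}

#' Tidy an EMSC fit
#' @param x An `emsc_result`.
#' @param ... Unused.
#' @return Tibble of component weights (`reference`, `substrate`,
#'   polynomial coefficients) and the residual norm.
#' @export
tidy.emsc_result <- function(x, ...) {
  tibble::tibble(
    term = c("cr", "cb", paste0("c", seq_along(x$cm) - 1)),
    estimate = c(x$cr, x$cb, x$cm),
    residual_norm = x$residual_norm)
}
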