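#' RBF-SVM configuration
#' @param C Penalty parameter (> 0).
#' @param gamma RBF kernel width (> 0).
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(C = 8, gamma = 2^-5) {
  C <- as.numeric(C); gamma <- as.numeric(gamma)
  if (!is.finite(C) || C <= 0) stop("C must be > 0", call. = FALSE)
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  structure(list(C = C, gamma = gamma), class = "svm_config")
}

#' Published parameter presets
#'
#' The two predictor configurations shipped with the package: `"pressc"`
#' (PseSSC features, n = 2, lambda = 13, w = 0.5, C = 8, gamma = 2^-5) and
#' `"expressc"` (ExPseSSC features, n = 1, lambda = 17, w = 0.2, C = 128,
#' gamma = 2^-7).
#'
#' @param name `"pressc"` or `"expressc"`.
#' @return List with elements `kind`, `params` ([psessc_params]) and `cfg`
#'   ([svm_config]).
#' @export
preset <- function(name = c("pressc", "expressc")) {
  name <- match.arg(name)
  if (name == "pressc") {
    list(kind = "PseSSC", params = psessc_params(2L, 13L, 0.5),
         cfg = svm_config(8, 2^-5))
  } else {
    list(kind = "ExPseSSC", params = psessc_params(1L, 17L, 0.2),
         cfg = svm_config(128, 2^-7))
  }
}

#' Confusion counts
#'
#' `n_pos`/`n_neg` are the class totals; `fn` the positives predicted
#' negative; `fp` the negatives predicted positive.
#'
#' @param n_pos,n_neg Class totals (each >= 1).
#' @param fn,fp Misclassification counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(n_pos, n_neg, fn, fp) {
  if (n_pos < 1 || n_neg < 1) {
    stop("both classes must be non-empty (n_pos, n_neg >= 1)", call. = FALSE)
  }
  if (fn < 0 || fn > n_pos) stop("fn must lie in [0, n_pos]", call. = FALSE)
  if (fp < 0 || fp > n_neg) stop("fp must lie in [0, n_neg]", call. = FALSE)
  structure(list(n_pos = as.numeric(n_pos), n_neg = as.numeric(n_neg),
                 fn = as.numeric(fn), fp = as.numeric(fp)),
            class = "confusion_counts")
}

#' Sn / Sp / Acc / MCC from confusion counts
#'
#' Sensitivity `Sn = 1 - fn/n_pos`, specificity `Sp = 1 - fp/n_neg`, overall
#' accuracy `Acc = 1 - (fn + fp)/(n_pos + n_neg)`, and the Matthews
#' correlation coefficient in its intuitive class-normalized form
#' `MCC = (1 - (fn/n_pos + fp/n_neg)) /
#'   sqrt((1 + (fp - fn)/n_pos) (1 + (fn - fp)/n_neg))`,
#' which is algebraically identical to the textbook MCC wherever both are
#' defined. When a factor under the square root vanishes the MCC is flagged
#' undefined (`mcc = NA`, `mcc_undefined = TRUE`).
#'
#' @param counts A [confusion_counts].
#' @return List with `sn`, `sp`, `acc`, `mcc`, `mcc_undefined`; class
#'   `metrics_result`.
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  np <- counts$n_pos; nn <- counts$n_neg
  fn <- counts$fn; fp <- counts$fp
  sn <- 1 - fn / np
  sp <- 1 - fp / nn
  acc <- 1 - (fn + fp) / (np + nn)
  d1 <- 1 + (fp - fn) / np
  d2 <- 1 + (fn - fp) / nn
  if (d1 <= 0 || d2 <= 0) {
    mcc <- NA_real_; undef <- TRUE
  } else {
    mcc <- (1 - (fn / np + fp / nn)) / sqrt(d1 * d2)
    undef <- FALSE
  }
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc,
                 mcc_undefined = undef), class = "metrics_result")
}

#' @export
print.metrics_result <- function(x, ...) {
  cat(sprintf("Sn = %.4f  Sp = %.4f  Acc = %.4f  MCC = %s\n",
              x$sn, x$sp, x$acc,
              if (x$mcc_undefined) "undefined" else sprintf("%.4f", x$mcc)))
  invisible(x)
}

# Assemble the numeric design matrix and +/-1 labels from feature vectors.
features_to_matrix <- function(features, require_labels = TRUE) {
  if (length(features) == 0L) {
    return(list(X = matrix(numeric(0), 0, 0), y = numeric(0),
                ids = character(0)))
  }
  dims <- vapply(features, function(f) length(f$values), integer(1))
  if (length(unique(dims)) != 1L) {
    stop(sprintf("feature dimension mismatch: %s",
                 paste(unique(dims), collapse = " vs ")), call. = FALSE)
  }
  X <- do.call(rbind, lapply(features, function(f) unname(f$values)))
  ids <- vapply(features, function(f) f$record_id, character(1))
  y <- rep(NA_real_, length(features))
  labs <- vapply(features, function(f) {
    if (is.null(f$label)) "unknown" else f$label
  }, character(1))
  y[labs == "positive"] <- 1
  y[labs == "negative"] <- -1
  if (require_labels && anyNA(y)) {
    stop("all records need a positive/negative label for training", call. = FALSE)
  }
  list(X = X, y = y, ids = ids,
       feature_names = names(features[[1L]]$values))
}

# Per-column linear scaling to [-1, 1] fitted on training data; constant
# columns map to 0.
scaling_fit <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  list(lo = lo, hi = hi)
}

scaling_apply <- function(X, sc) {
  span <- sc$hi - sc$lo
  span[span == 0] <- 1
  Xs <- sweep(X, 2L, sc$lo)
  Xs <- sweep(Xs, 2L, span, "/") * 2 - 1
  const <- which(sc$hi == sc$lo)
  if (length(const)) Xs[, const] <- 0
  Xs
}

#' Train an RBF-SVM model bundle
#'
#' Fits per-feature linear scaling to `[-1, 1]` on the training data, then a
#' C-SVC with RBF kernel by sequential minimal optimization. The returned
#' bundle carries everything needed to reproduce predictions: support
#' vectors, coefficients, intercept, scaling bounds, the feature kind and
#' parameters, and creation metadata.
#'
#' @param features List of labelled `feature_vector`s (both classes present).
#' @param cfg An [svm_config].
#' @param seed Recorded in the bundle metadata (training itself is
#'   deterministic).
#' @param convention Status convention the features were built with.
#' @param table The [free_energy_table] used.
#' @return Object of class `model_bundle`.
#' @export
train <- function(features, cfg = svm_config(), seed = 1L,
                  convention = "own-first", table = free_energy_table()) {
  fm <- features_to_matrix(features)
  if (length(unique(fm$y)) < 2L) {
    stop("training data contains a single class; need both positives and negatives",
         call. = FALSE)
  }
  sc <- scaling_fit(fm$X)
  Xs <- scaling_apply(fm$X, sc)
  fit <- .svm_smo_cpp(Xs, fm$y, cfg$C, cfg$gamma, 1e-3, 100000L)
  keep <- which(fit$alpha > 1e-12)
  structure(list(
    version = 1L,
    kind = features[[1L]]$kind,
    params = features[[1L]]$params,
    cfg = cfg,
    scaling = sc,
    sv = Xs[keep, , drop = FALSE],
    coef = fit$alpha[keep] * fm$y[keep],
    b = fit$b,
    feature_names = fm$feature_names,
    convention = convention,
    energy_table = unclass(table),
    meta = list(seed = seed, iterations = fit$iterations,
                converged = fit$converged, n_train = nrow(Xs),
                package_version = as.character(utils::packageVersion("psessc")))
  ), class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s (n=%d lambda=%d w=%g) C=%g gamma=%g; %d SVs of %d samples\n",
              x$kind, x$params$n, x$params$lam, x$params$w, x$cfg$C,
              x$cfg$gamma, nrow(x$sv), x$meta$n_train))
  invisible(x)
}

#' Predict with a model bundle
#'
#' @param object A `model_bundle`.
#' @param features List of `feature_vector`s with the bundle's dimension.
#' @param ... Unused.
#' @return Data frame with `id`, `label` (`"Real Pre-miRNA"` /
#'   `"False Pre-miRNA"`) and the real-valued `decision` score (positive
#'   side = real).
#' @export
predict.model_bundle <- function(object, features, ...) {
  if (length(features) == 0L) {
    return(data.frame(id = character(0), label = character(0),
                      decision = numeric(0), stringsAsFactors = FALSE))
  }
  fm <- features_to_matrix(features, require_labels = FALSE)
  if (ncol(fm$X) != length(object$feature_names)) {
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(fm$X), length(object$feature_names)), call. = FALSE)
  }
  Xs <- scaling_apply(fm$X, object$scaling)
  dec <- .svm_decision_cpp(object$sv, object$coef, object$b,
                           object$cfg$gamma, Xs)
  data.frame(id = fm$ids,
             label = ifelse(dec >= 0, "Real Pre-miRNA", "False Pre-miRNA"),
             decision = dec, stringsAsFactors = FALSE)
}

#' Persist / load a model bundle
#'
#' A bundle is stored as a single versioned file; a reloaded bundle produces
#' identical predictions.
#' @param model A `model_bundle`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "model_bundle"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model` returns the `model_bundle`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "model_bundle") || is.null(model$version)) {
    stop(sprintf("'%s' is not a psessc model bundle", path), call. = FALSE)
  }
  model
}

# Stratified fold assignment: within each class, seeded shuffle then modulo
# split; returns an integer fold id per sample.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' ROC points from decision scores
#' @param decision Numeric scores (higher = more positive).
#' @param truth Numeric +1/-1 or logical truth.
#' @return Data frame of `fpr`, `tpr` thresholded at every distinct score.
#' @export
roc_points <- function(decision, truth) {
  truth <- as.numeric(truth)
  if (all(truth %in% c(0, 1))) truth <- ifelse(truth == 1, 1, -1)
  ord <- order(decision, decreasing = TRUE)
  d <- decision[ord]; t <- truth[ord]
  np <- sum(t > 0); nn <- sum(t < 0)
  tp <- cumsum(t > 0); fp <- cumsum(t < 0)
  keep <- c(which(diff(d) != 0), length(d))
  data.frame(fpr = c(0, fp[keep] / nn), tpr = c(0, tp[keep] / np))
}

#' AUC by the rank statistic (ties get half credit)
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(decision, truth) {
  truth <- as.numeric(truth)
  if (all(truth %in% c(0, 1))) truth <- ifelse(truth == 1, 1, -1)
  np <- sum(truth > 0); nn <- sum(truth < 0)
  if (np == 0 || nn == 0) stop("AUC needs both classes", call. = FALSE)
  r <- rank(decision)  # average ranks: half credit for ties
  (sum(r[truth > 0]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated evaluation
#'
#' Every held-out sample is scored by a model trained without it, with the
#' feature scaling refitted inside each training split (no leakage). Counts
#' are aggregated into [confusion_counts]; the ROC is built from the pooled
#' decision values and the AUC from the rank statistic.
#'
#' @param features Labelled `feature_vector`s.
#' @param cfg An [svm_config].
#' @param scheme `"kfold"` or `"jackknife"` (leave-one-out).
#' @param k Number of folds for `"kfold"` (2 <= k <= sample count).
#' @param seed Seed for the stratified fold assignment.
#' @return List with `counts` ([confusion_counts]), `metrics`
#'   ([metrics_from_counts]), `roc` (data frame), `auc`, `decision`,
#'   `truth`; class `cv_result`.
#' @export
cross_validate <- function(features, cfg = svm_config(),
                           scheme = c("kfold", "jackknife"), k = 5L,
                           seed = 1L) {
  scheme <- match.arg(scheme)
  fm <- features_to_matrix(features)
  n <- length(features)
  if (scheme == "jackknife") {
    folds <- seq_len(n)
    k <- n
  } else {
    k <- as.integer(k)
    if (k < 2L || k > n) {
      stop(sprintf("k = %d must lie in [2, %d]", k, n), call. = FALSE)
    }
    # k == n degenerates to leave-one-out: identical splits to jackknife
    folds <- if (k == n) seq_len(n) else stratified_folds(fm$y, k, seed)
  }
  dec <- numeric(n)
  for (fold in seq_len(k)) {
    test_idx <- which(folds == fold)
    if (length(test_idx) == 0L) next
    train_idx <- setdiff(seq_len(n), test_idx)
    ytr <- fm$y[train_idx]
    if (length(unique(ytr)) < 2L) {
      stop("a training split lost one class entirely; use fewer folds",
           call. = FALSE)
    }
    sc <- scaling_fit(fm$X[train_idx, , drop = FALSE])
    Xtr <- scaling_apply(fm$X[train_idx, , drop = FALSE], sc)
    Xte <- scaling_apply(fm$X[test_idx, , drop = FALSE], sc)
    fit <- .svm_smo_cpp(Xtr, ytr, cfg$C, cfg$gamma, 1e-3, 100000L)
    keep <- which(fit$alpha > 1e-12)
    dec[test_idx] <- .svm_decision_cpp(Xtr[keep, , drop = FALSE],
                                       fit$alpha[keep] * ytr[keep],
                                       fit$b, cfg$gamma, Xte)
  }
  pred_pos <- dec >= 0
  counts <- confusion_counts(
    n_pos = sum(fm$y > 0), n_neg = sum(fm$y < 0),
    fn = sum(fm$y > 0 & !pred_pos), fp = sum(fm$y < 0 & pred_pos))
  structure(list(counts = counts, metrics = metrics_from_counts(counts),
                 roc = roc_points(dec, fm$y), auc = auc_rank(dec, fm$y),
                 decision = dec, truth = fm$y, scheme = scheme, k = k,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s cross-validation (k = %d):\n", x$scheme, x$k))
  print(x$metrics)
  cat(sprintf("AUC = %.4f\n", x$auc))
  invisible(x)
}

#' Enumerate the (n, lambda, w) parameter grid
#'
#' Defaults follow the published search protocol: `n` in 1..4, `lambda` in
#' 1..20, `w` in 0.1..1.0 by 0.1 — 800 cells. The 11-point `w` grid
#' including 0 is available by passing `w_values = seq(0, 1, 0.1)`.
#'
#' @param n_values,lam_values,w_values Grid axes.
#' @return Data frame of all (n, lam, w) combinations.
#' @export
enumerate_param_grid <- function(n_values = 1:4, lam_values = 1:20,
                                 w_values = seq(0.1, 1, by = 0.1)) {
  expand.grid(n = n_values, lam = lam_values, w = w_values,
              KEEP.OUT.ATTRS = FALSE)
}

#' Default (C, gamma) sub-grid
#'
#' The conventional exponential grid of the LIBSVM grid-search script:
#' `C = 2^-5 ... 2^15`, `gamma = 2^-15 ... 2^3`, both stepped by a factor
#' of 4.
#' @return List with numeric vectors `C` and `gamma`.
#' @export
default_svm_grid <- function() {
  list(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

#' Hyperparameter grid search
#'
#' For every (n, lambda, w) cell, features are regenerated from the folded
#' records, then every (C, gamma) pair is scored by stratified k-fold CV
#' accuracy. Cells whose lambda reaches the shortest sequence length are
#' skipped with a warning. The argmax is returned with deterministic
#' tie-breaking: higher accuracy, then smaller lambda, n, w, C, gamma.
#'
#' @param rnas Folded, labelled [annotated_rna] records.
#' @param kind `"PseSSC"` or `"ExPseSSC"`.
#' @param param_grid Data frame from [enumerate_param_grid] (or a subset).
#' @param svm_grid List with `C` and `gamma` vectors.
#' @param folds CV folds (default 5).
#' @param seed Fold-assignment seed.
#' @param table,convention,b_values Passed to [featurize].
#' @return List with `best` (`params`, `cfg`, `accuracy`) and `cells`
#'   (per-combination accuracy table).
#' @export
grid_search <- function(rnas, kind = "PseSSC",
                        param_grid = enumerate_param_grid(),
                        svm_grid = default_svm_grid(), folds = 5L, seed = 1L,
                        table = free_energy_table(),
                        convention = "own-first", b_values = NULL) {
  min_len <- min(vapply(rnas, function(r) nchar(r$residues), integer(1)))
  rows <- list()
  for (ci in seq_len(nrow(param_grid))) {
    n <- param_grid$n[ci]; lam <- param_grid$lam[ci]; w <- param_grid$w[ci]
    if (lam >= min_len) {
      warning(sprintf("skipping grid cell (n=%d, lambda=%d, w=%g): lambda >= min sequence length %d",
                      n, lam, w, min_len), call. = FALSE)
      next
    }
    params <- psessc_params(n, lam, w)
    feats <- featurize(rnas, kind = kind, params = params, table = table,
                       convention = convention, b_values = b_values)
    for (C in svm_grid$C) {
      for (gamma in svm_grid$gamma) {
        cv <- cross_validate(feats, svm_config(C, gamma), "kfold",
                             k = folds, seed = seed)
        rows[[length(rows) + 1L]] <-
          data.frame(n = n, lam = lam, w = w, C = C, gamma = gamma,
                     acc = cv$metrics$acc)
      }
    }
  }
  if (length(rows) == 0L) stop("no usable grid cells", call. = FALSE)
  cells <- do.call(rbind, rows)
  ord <- order(-cells$acc, cells$lam, cells$n, cells$w, cells$C, cells$gamma)
  bestrow <- cells[ord[1L], ]
  list(best = list(params = psessc_params(bestrow$n, bestrow$lam, bestrow$w),
                   cfg = svm_config(bestrow$C, bestrow$gamma),
                   accuracy = bestrow$acc),
       cells = cells)
}
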