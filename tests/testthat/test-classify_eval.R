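test_that("metric boundary cases reproduce exactly", {
  m <- metrics_from_counts(confusion_counts(100, 100, 0, 0))
  expect_equal(c(m$sn, m$sp, m$acc, m$mcc), c(1, 1, 1, 1))

  m <- metrics_from_counts(confusion_counts(100, 80, 50, 40))
  expect_equal(m$mcc, 0)

  m <- metrics_from_counts(confusion_counts(100, 100, 100, 100))
  expect_equal(m$mcc, -1)
  expect_equal(m$acc, 0)

  expect_error(confusion_counts(0, 10, 0, 0), "non-empty")
  expect_error(confusion_counts(10, 10, 11, 0), "fn")
})

test_that("class-normalized MCC equals the textbook MCC where defined", {
  for (np in c(1, 3, 7, 20)) {
    for (nn in c(1, 4, 20)) {
      for (fn in 0:np) {
        for (fp in 0:nn) {
          m <- metrics_from_counts(confusion_counts(np, nn, fn, fp))
          ref <- oracle_mcc(tp = np - fn, tn = nn - fp, fp = fp, fn = fn)
          if (m$mcc_undefined) {
            expect_true(is.na(ref))
          } else {
            expect_equal(m$mcc, ref, tolerance = 1e-12)
          }
          # Acc = (Sn N+ + Sp N-) / (N+ + N-) identically
          expect_equal(m$acc, (m$sn * np + m$sp * nn) / (np + nn))
        }
      }
    }
  }
})

make_separable_features <- function(n_per_class = 10, seed = 2) {
  set.seed(seed)
  rnas <- simulate_hairpin_set(n_per_class, n_per_class,
                               pos_spec = hairpin_spec(stem_len = 20),
                               neg_spec = hairpin_spec(stem_len = 6,
                                                       flank_len = 19),
                               seed = seed)
  featurize(rnas, "PseSSC", psessc_params(1, 5, 0.5))
}

test_that("train/predict on separable classes reproduces the labels", {
  feats <- make_separable_features()
  model <- train(feats, svm_config(8, 2^-5), seed = 1)
  pred <- predict(model, feats)
  truth <- ifelse(vapply(feats, function(f) f$label, "") == "positive",
                  "Real Pre-miRNA", "False Pre-miRNA")
  expect_identical(pred$label, truth)

  # persisted and reloaded bundle predicts identically
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  pred2 <- predict(load_model(path), feats)
  expect_identical(pred, pred2)

  expect_identical(nrow(predict(model, list())), 0L)
  expect_error(predict(model, featurize(
    simulate_hairpin_set(2, 0, seed = 1), "PseSSC", psessc_params(1, 3, 0.5))),
    "dimension")
})

test_that("conflicting duplicate labels train without crashing", {
  feats <- make_separable_features(6)
  dup <- feats[[1L]]
  dup$label <- "negative"
  dup$record_id <- "dup"
  feats2 <- c(feats, list(dup))
  model <- train(feats2, svm_config(1, 0.5))
  pred <- predict(model, feats2)
  truth <- ifelse(vapply(feats2, function(f) f$label, "") == "positive",
                  "Real Pre-miRNA", "False Pre-miRNA")
  expect_lt(mean(pred$label == truth), 1)  # cannot fit contradictory labels
})

test_that("training requires two classes", {
  feats <- make_separable_features(4)
  pos_only <- Filter(function(f) identical(f$label, "positive"), feats)
  expect_error(train(pos_only), "single class")
})

test_that("SMO solution satisfies the KKT conditions (independent check)", {
  feats <- make_separable_features(8, seed = 14)
  fm <- psessc:::features_to_matrix(feats)
  sc <- psessc:::scaling_fit(fm$X)
  Xs <- psessc:::scaling_apply(fm$X, sc)
  for (cfg in list(svm_config(8, 2^-5), svm_config(128, 2^-7))) {
    fit <- psessc:::.svm_smo_cpp(Xs, fm$y, cfg$C, cfg$gamma, 1e-3, 100000L)
    a <- fit$alpha
    expect_true(all(a >= 0 & a <= cfg$C))
    expect_lt(abs(sum(a * fm$y)), 1e-6)
    K <- exp(-cfg$gamma * as.matrix(dist(Xs))^2)
    G <- as.numeric(K %*% (a * fm$y)) * fm$y - 1
    up <- (fm$y > 0 & a < cfg$C) | (fm$y < 0 & a > 0)
    lo <- (fm$y > 0 & a > 0) | (fm$y < 0 & a < cfg$C)
    gap <- max(-fm$y[up] * G[up]) - min(-fm$y[lo] * G[lo])
    expect_lt(gap, 1e-3 + 1e-8)
  }
})

test_that("cross_validate: separable jackknife is perfect; ties give AUC 0.5", {
  feats <- make_separable_features(6, seed = 8)
  res <- cross_validate(feats, svm_config(8, 2^-5), scheme = "jackknife")
  expect_equal(res$metrics$acc, 1)
  expect_equal(res$auc, 1)

  expect_equal(auc_rank(rep(0.3, 10), c(rep(1, 5), rep(-1, 5))), 0.5)

  expect_error(cross_validate(feats, k = 1), "k = 1")
  expect_error(cross_validate(feats, k = 1000), "k = 1000")
})

test_that("k = sample count matches jackknife; order does not matter", {
  feats <- make_separable_features(5, seed = 10)
  jk <- cross_validate(feats, svm_config(2, 0.1), scheme = "jackknife")
  kn <- cross_validate(feats, svm_config(2, 0.1), scheme = "kfold",
                       k = length(feats))
  expect_identical(jk$counts, kn$counts)

  set.seed(1)
  perm <- sample(seq_along(feats))
  jk2 <- cross_validate(feats[perm], svm_config(2, 0.1), scheme = "jackknife")
  expect_identical(jk$counts, jk2$counts)
})

test_that("rank AUC equals trapezoidal area under the ROC polygon", {
  set.seed(44)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    truth <- sample(c(1, -1), n, TRUE)
    if (length(unique(truth)) < 2) next
    scores <- round(rnorm(n), 1)  # rounding forces ties
    roc <- roc_points(scores, truth)
    expect_equal(auc_rank(scores, truth), oracle_trapezoid_auc(roc),
                 tolerance = 1e-12)
  }
})

test_that("grid_search returns argmax with deterministic tie-breaking", {
  set.seed(18)
  rnas <- simulate_hairpin_set(8, 8,
                               pos_spec = hairpin_spec(stem_len = 18),
                               neg_spec = hairpin_spec(stem_len = 5,
                                                       flank_len = 18),
                               seed = 18)
  one <- grid_search(rnas, param_grid = data.frame(n = 1, lam = 3, w = 0.5),
                     svm_grid = list(C = 8, gamma = 2^-5), folds = 4, seed = 2)
  expect_equal(one$best$params$n, 1L)
  expect_equal(one$best$params$lam, 3L)
  expect_identical(nrow(one$cells), 1L)

  # separable data: both lambda cells reach accuracy 1; smaller lambda wins
  two <- grid_search(rnas, param_grid = data.frame(n = 1, lam = c(3, 2),
                                                   w = 0.5),
                     svm_grid = list(C = 8, gamma = 2^-5), folds = 4, seed = 2)
  expect_equal(max(two$cells$acc), 1)
  expect_equal(two$best$params$lam, 2L)

  # lambda >= min length: cell skipped with a warning, not a crash
  expect_warning(
    sk <- grid_search(rnas, param_grid = data.frame(n = 1, lam = c(3, 500),
                                                    w = 0.5),
                      svm_grid = list(C = 8, gamma = 2^-5), folds = 4,
                      seed = 2),
    "skipping")
  expect_identical(nrow(sk$cells), 1L)
})
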