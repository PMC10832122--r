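test_that("standardization uses train-fitted population moments", {
  tr <- matrix(c(1, 2, 3, 5, 5, 5), 3,
               dimnames = list(NULL, c("a", "const")))
  ap <- matrix(c(2, 4, 5, 5), 2, dimnames = list(NULL, c("a", "const")))
  sc <- standardize(tr, ap)
  expect_equal(sc$train[, "a"], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  # constant column: centered, never divided by zero
  expect_equal(sc$train[, "const"], c(0, 0, 0))
  expect_false(any(is.nan(sc$apply)))
  # train-fitted parameters applied to apply rows
  expect_equal(sc$apply[, "a"], (c(2, 4) - 2) / sc$scale[["a"]])
  # reapplying to the train matrix reproduces zero means
  expect_equal(unname(colMeans(sc$train)), c(0, 0))
  colnames(ap) <- c("a", "wrong")
  expect_error(standardize(tr, ap), "mismatch")
  expect_error(standardize(matrix(numeric(0), 0, 1)), "empty")
})

test_that("training attains perfect separation on a separable fixture and is reproducible", {
  d <- makeSeparable(n = 40, seed = 3)
  fit1 <- trainEnsemble(d$X, d$y, seed = 9)
  fit2 <- trainEnsemble(d$X, d$y, seed = 9)
  p1 <- predictScores(fit1, d$X)
  p2 <- predictScores(fit2, d$X)
  expect_identical(p1, p2)
  expect_equal(mean((p1$classification == "Pathogenic") == (d$y == 1)), 1)
  expect_true(all(p1$svm_score >= 0 & p1$svm_score <= 1))
  expect_true(all(p1$xgb_score >= 0 & p1$xgb_score <= 1))
  expect_error(trainEnsemble(d$X, rep(1, 40)), "both classes")
  expect_error(trainEnsemble(d$X, d$y[-1]), "length")
})

test_that("the ensemble decision rule matches the strict either-model threshold", {
  expect_equal(ensembleClassify(0.94, 0.00)$classification, "Pathogenic")
  expect_equal(ensembleClassify(0.05, 0.49)$classification, "Benign")
  expect_equal(ensembleClassify(0.02, 0.63)$classification, "Pathogenic")
  expect_equal(ensembleClassify(0.5, 0.5)$classification, "Benign")
  expect_equal(ensembleClassify(0.3, 0.4)$confidence, 0.7)
  expect_error(ensembleClassify(1.2, 0.1), "probabilities")
  expect_error(ensembleClassify(0.4, -0.1), "probabilities")
  # monotone: raising either score never flips Pathogenic -> Benign
  set.seed(5)
  for (i in 1:50) {
    s <- runif(2)
    base <- ensembleClassify(s[1], s[2])$classification
    up1 <- ensembleClassify(min(1, s[1] + runif(1)), s[2])$classification
    up2 <- ensembleClassify(s[1], min(1, s[2] + runif(1)))$classification
    if (base == "Pathogenic") {
      expect_equal(up1, "Pathogenic")
      expect_equal(up2, "Pathogenic")
    }
  }
})

test_that("LOOCV produces one held-out score pair per sample without leakage", {
  d <- makeSeparable(n = 24, seed = 4)
  cv <- loocvEnsemble(d$X, d$y, seed = 2)
  expect_equal(nrow(cv), 24)
  expect_equal(rocAUC(cv$confidence, d$y), 1)
  expect_error(loocvEnsemble(d$X[1:2, ], d$y[1:2]), "n >= 3")
  # leakage guard: duplicating one row leaves other folds' scores intact
  X2 <- rbind(d$X, d$X[1, , drop = FALSE])
  cv2 <- loocvEnsemble(X2, c(d$y, d$y[1]), seed = 2)
  expect_equal(cor(cv$svm_score, cv2$svm_score[1:24]), 1, tolerance = 0.05)
})

test_that("grid search is an argmax over the grid with deterministic ties", {
  d <- makeSeparable(n = 30, seed = 6)
  single <- gridSearchEnsemble(d$X, d$y,
                               svm_grid = list(C = 1, gamma = list("scale"),
                                               kernel = "radial"),
                               xgb_grid = list(n_estimators = 50, max_depth = 2),
                               nfolds = 3, seed = 1)
  expect_equal(single$spec$C, 1)
  expect_equal(single$spec$n_estimators, 50L)
  small <- gridSearchEnsemble(d$X, d$y,
                              svm_grid = list(C = c(0.1, 10),
                                              gamma = list(0.1, "scale"),
                                              kernel = c("radial", "linear")),
                              xgb_grid = list(n_estimators = c(20, 50),
                                              max_depth = c(2, 3)),
                              nfolds = 3, seed = 1)
  best_f1 <- small$svm_results$f1[small$svm_results$C == small$spec$C &
                                  small$svm_results$kernel == small$spec$kernel][1]
  expect_true(all(small$svm_results$f1 <= max(small$svm_results$f1)))
  expect_equal(max(small$svm_results$f1),
               max(best_f1, max(small$svm_results$f1)))
  rerun <- gridSearchEnsemble(d$X, d$y,
                              svm_grid = list(C = c(0.1, 10),
                                              gamma = list(0.1, "scale"),
                                              kernel = c("radial", "linear")),
                              xgb_grid = list(n_estimators = c(20, 50),
                                              max_depth = c(2, 3)),
                              nfolds = 3, seed = 1)
  expect_identical(small$spec, rerun$spec)
})

test_that("permutation importance isolates informative features", {
  d <- makeSeparable(n = 60, p_noise = 4, seed = 8)
  fit <- trainEnsemble(d$X, d$y, seed = 1)
  imp <- permutationImportance(fit, d$X, d$y, n_repeats = 5, seed = 2)
  expect_true(imp$feature[1] %in% c("inf1", "inf2"))
  # constant feature: permutation is a distributional no-op
  Xc <- cbind(d$X, flat = 1)
  fitc <- trainEnsemble(Xc, d$y, seed = 1)
  impc <- permutationImportance(fitc, Xc, d$y, n_repeats = 5, seed = 2)
  expect_lt(abs(impc$importance[impc$feature == "flat"]), 1e-8)
  # duplicated informative feature shares the signal
  Xd <- cbind(d$X, inf1_copy = d$X[, "inf1"])
  fitd <- trainEnsemble(Xd, d$y, seed = 1)
  impd <- permutationImportance(fitd, Xd, d$y, n_repeats = 5, seed = 2)
  solo <- imp$importance[imp$feature == "inf1"]
  expect_lte(impd$importance[impd$feature == "inf1"], solo + 1e-8)
  expect_lte(impd$importance[impd$feature == "inf1_copy"], solo + 1e-8)
})

test_that("correlation pruning keeps the most predictive member of each group", {
  d <- makeSeparable(n = 50, p_noise = 2, seed = 10)
  # exact duplicate: exactly one survivor from the pair
  X <- cbind(d$X, inf1_dup = d$X[, "inf1"])
  pr <- correlationPrune(X, d$y, r_threshold = 0.9)
  expect_equal(sum(c("inf1", "inf1_dup") %in% pr$retained), 1)
  # uncorrelated features all survive
  pr2 <- correlationPrune(d$X[, c("inf1", "noise1", "noise2")], d$y)
  expect_setequal(pr2$retained, c("inf1", "noise1", "noise2"))
  # r = 0.95 pair: the informative member survives
  set.seed(2)
  informative <- d$X[, "inf1"]
  noisy_twin <- informative + rnorm(50, 0, sqrt(var(informative) * (1 / 0.9 - 1)))
  X3 <- cbind(inf = informative, twin = noisy_twin,
              junk = rnorm(50))
  expect_gt(abs(cor(X3[, "inf"], X3[, "twin"])), 0.9)
  pr3 <- correlationPrune(X3, d$y, r_threshold = 0.9)
  expect_true("inf" %in% pr3$retained)
  expect_false("twin" %in% pr3$retained)
  expect_error(correlationPrune(X3, d$y, r_threshold = 0), "r_threshold")
})

test_that("model bundles round-trip through disk", {
  d <- makeSeparable(n = 30, seed = 12)
  fit <- trainEnsemble(d$X, d$y, seed = 4)
  dir <- withr::local_tempdir()
  saveModelBundle(fit, dir)
  back <- loadModelBundle(dir)
  expect_equal(predictScores(back, d$X), predictScores(fit, d$X),
               tolerance = 1e-6)
  expect_identical(featureNames(back), featureNames(fit))
  expect_error(loadModelBundle(file.path(dir, "nope")), "not found")
  # schema guard on prediction
  Xbad <- d$X[, rev(colnames(d$X))]
  expect_error(predictScores(fit, Xbad), "schema mismatch")
})
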