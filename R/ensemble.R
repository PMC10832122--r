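#' Feature standardization (z-scaling)
#'
#' Fits per-feature centering/scaling constants on the training rows only
#' and applies them to both matrices. Scaling uses the population (divide by
#' n) standard deviation, so a column `c(1, 2, 3)` scales to
#' `c(-1.2247, 0, 1.2247)`. Constant columns are centered but not divided
#' (their fitted sd is stored as 1), so no division by zero occurs.
#'
#' @param train numeric matrix of training rows (non-empty).
#' @param apply optional matrix to transform with the train-fitted
#'   constants; must have identical column names.
#' @return list: `train` (scaled), `apply` (scaled, or `NULL`),
#'   `center`, `scale` (fitted constants).
#' @export
standardize <- function(train, apply = NULL) {
  sc <- fitScaler(train)
  list(train = applyScaler(sc, train),
       apply = if (is.null(apply)) NULL else applyScaler(sc, apply),
       center = sc$center, scale = sc$scale)
}

fitScaler <- function(train) {
  if (!is.matrix(train) || nrow(train) == 0) stop("train matrix is empty")
  ctr <- colMeans(train)
  sdev <- sqrt(colMeans(sweep(train, 2, ctr)^2))   # population sd
  sdev[sdev == 0] <- 1
  list(center = ctr, scale = sdev)
}

applyScaler <- function(scaler, X) {
  if (!identical(colnames(X), names(scaler$center)))
    stop("feature-name mismatch between scaler and matrix")
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

#' Hyperparameter specification for the ensemble
#'
#' @param C SVM soft-margin cost.
#' @param gamma SVM RBF width; `"scale"` uses `1 / (p * var(X))` computed on
#'   the (scaled) training matrix.
#' @param kernel `"radial"` or `"linear"`.
#' @param n_estimators boosting rounds for the tree model.
#' @param max_depth tree depth.
#' @param features optional feature subset (default: all columns).
#' @return list of class `"trModelSpec"`.
#' @export
modelSpec <- function(C = 1, gamma = "scale", kernel = "radial",
                      n_estimators = 100L, max_depth = 3L,
                      features = NULL) {
  kernel <- match.arg(kernel, c("radial", "linear"))
  structure(list(C = C, gamma = gamma, kernel = kernel,
                 n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth), features = features),
            class = "trModelSpec")
}

resolveGamma <- function(gamma, X) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(X))
    if (!is.finite(v) || v == 0) v <- 1
    1 / (ncol(X) * v)
  } else as.numeric(gamma)
}

normalizeLabels <- function(labels, n) {
  if (length(labels) != n) stop("label vector length does not match rows")
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    y <- ifelse(tolower(labels) %in% c("pathogenic", "1", "positive"), 1L, 0L)
  } else y <- as.integer(labels != 0)
  if (length(unique(y)) < 2) stop("need both classes present in labels")
  y
}

#' Train the SVM + XGB ensemble
#'
#' Fits a Platt-calibrated SVM on standardized features and a
#' gradient-boosted tree model (logistic objective) on raw features. Both
#' expose the probability of the pathogenic class. The fit is deterministic
#' for a fixed seed (single-threaded boosting).
#'
#' @param X numeric feature matrix (rows = loci) with column names.
#' @param labels pathogenic/benign labels (`"pathogenic"`/`"benign"`,
#'   1/0 or logical); both classes required.
#' @param spec a [modelSpec()].
#' @param seed integer RNG seed.
#' @return A [TREnsemble-class].
#' @export
trainEnsemble <- function(X, labels, spec = modelSpec(), seed = 1L) {
  y <- normalizeLabels(labels, nrow(X))
  if (!is.null(spec$features)) X <- X[, spec$features, drop = FALSE]
  scaler <- fitScaler(X)
  Xs <- applyScaler(scaler, X)
  yf <- factor(ifelse(y == 1, "pathogenic", "benign"),
               levels = c("benign", "pathogenic"))
  set.seed(seed)
  svm_fit <- e1071::svm(x = Xs, y = yf, kernel = spec$kernel,
                        cost = spec$C,
                        gamma = resolveGamma(spec$gamma, Xs),
                        probability = TRUE, scale = FALSE)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgb_fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = spec$max_depth,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = spec$n_estimators, verbose = 0)
  new("TREnsemble", svm = svm_fit, xgb = xgb_fit, scaler = scaler,
      features = colnames(X), spec = unclass(spec), seed = as.integer(seed))
}

memberScores <- function(object, X, which = c("svm", "xgb")) {
  which <- match.arg(which)
  if (!identical(colnames(X), object@features))
    stop("feature schema mismatch between model and prediction matrix; ",
         "refusing to predict on misaligned columns")
  if (which == "svm") {
    Xs <- applyScaler(object@scaler, X)
    pr <- attr(stats::predict(object@svm, Xs, probability = TRUE),
               "probabilities")
    unname(pr[, "pathogenic"])
  } else {
    as.numeric(stats::predict(object@xgb,
                              xgboost::xgb.DMatrix(X, nthread = 1)))
  }
}

#' Score loci with a fitted ensemble
#'
#' @param object a [TREnsemble-class].
#' @param X feature matrix with the model's schema (same columns, same
#'   order; anything else is an error).
#' @return data.frame: `svm_score`, `xgb_score`, `classification`
#'   (`"Pathogenic"` iff either score > 0.5), `confidence` (score sum).
#' @export
predictScores <- function(object, X) {
  svm <- memberScores(object, X, "svm")
  xgb <- memberScores(object, X, "xgb")
  out <- ensembleClassify(svm, xgb)
  rownames(out) <- rownames(X)
  out
}

#' Ensemble decision rule
#'
#' Pathogenic iff either model's probability strictly exceeds 0.5;
#' confidence is the sum of the two probabilities (range 0-2). A pair of
#' exactly (0.5, 0.5) is benign.
#'
#' @param svm_score,xgb_score numeric vectors of probabilities in \[0, 1\].
#' @return data.frame: `svm_score`, `xgb_score`, `classification`,
#'   `confidence`.
#' @examples
#' ensembleClassify(0.94, 0.00)   # Pathogenic
#' ensembleClassify(0.05, 0.49)   # Benign
#' @export
ensembleClassify <- function(svm_score, xgb_score) {
  svm_score <- as.numeric(svm_score); xgb_score <- as.numeric(xgb_score)
  if (length(svm_score) != length(xgb_score))
    stop("score vectors must have equal length")
  if (anyNA(svm_score) || anyNA(xgb_score) ||
      any(svm_score < 0 | svm_score > 1) || any(xgb_score < 0 | xgb_score > 1))
    stop("scores must be probabilities in [0, 1]")
  data.frame(svm_score = svm_score, xgb_score = xgb_score,
             classification = ifelse(svm_score > 0.5 | xgb_score > 0.5,
                                     "Pathogenic", "Benign"),
             confidence = svm_score + xgb_score,
             stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validation of the ensemble
#'
#' One fold per sample: the scaler and both models are refit on the other
#' `n - 1` samples (no leakage of the held-out row into scaling or
#' fitting), and the held-out sample is scored. Folds whose training part
#' loses one class entirely raise an error.
#'
#' @param X feature matrix (`n >= 3` rows).
#' @param labels class labels (see [trainEnsemble()]).
#' @param spec a [modelSpec()].
#' @param seed integer seed (shared across folds).
#' @return data.frame with one row per sample: `svm_score`, `xgb_score`,
#'   `classification`, `confidence`, `label`.
#' @export
loocvEnsemble <- function(X, labels, spec = modelSpec(), seed = 1L) {
  n <- nrow(X)
  if (n < 3) stop("LOOCV needs n >= 3")
  y <- normalizeLabels(labels, n)
  svm <- numeric(n); xgb <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2)
      stop("fold ", i, " leaves a single class in the training part")
    fit <- trainEnsemble(X[-i, , drop = FALSE], ytr, spec = spec, seed = seed)
    svm[i] <- memberScores(fit, X[i, , drop = FALSE], "svm")
    xgb[i] <- memberScores(fit, X[i, , drop = FALSE], "xgb")
  }
  out <- ensembleClassify(svm, xgb)
  out$label <- ifelse(y == 1, "pathogenic", "benign")
  rownames(out) <- rownames(X)
  out
}

cvFolds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

cvF1 <- function(X, y, spec, which, nfolds, seed) {
  fold <- cvFolds(nrow(X), nfolds, seed)
  pred <- numeric(nrow(X))
  for (f in unique(fold)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) return(NA_real_)
    fit <- trainEnsemble(X[tr, , drop = FALSE], y[tr], spec, seed = seed)
    pred[!tr] <- memberScores(fit, X[!tr, , drop = FALSE], which)
  }
  tp <- sum(pred > 0.5 & y == 1); fp <- sum(pred > 0.5 & y == 0)
  fn <- sum(pred <= 0.5 & y == 1)
  if (tp + fp == 0 || tp + fn == 0) return(0)  # degenerate: rank last
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Exhaustive hyperparameter grid search
#'
#' Scores every point of the SVM grid (C x gamma x kernel) and the XGB grid
#' (n_estimators x max_depth) by k-fold cross-validated F1 of that member,
#' and returns the best combined [modelSpec()]. Ties are broken by
#' first-in-grid order, so the search is deterministic for a fixed seed.
#'
#' @param X feature matrix.
#' @param labels class labels.
#' @param svm_grid list with vectors `C`, `gamma`, `kernel`.
#' @param xgb_grid list with vectors `n_estimators`, `max_depth`.
#' @param nfolds folds for the selection metric.
#' @param seed integer seed (folds and fits).
#' @return list: `spec` (best [modelSpec()]), `svm_results`, `xgb_results`
#'   (data.frames of grid points with their CV-F1).
#' @export
gridSearchEnsemble <- function(X, labels,
                               svm_grid = list(C = c(0.1, 1, 10, 100),
                                               gamma = list(0.01, 0.1, 1, "scale"),
                                               kernel = c("radial", "linear")),
                               xgb_grid = list(n_estimators = c(50, 100, 200, 400),
                                               max_depth = c(2, 3, 4, 6)),
                               nfolds = 5L, seed = 1L) {
  y <- normalizeLabels(labels, nrow(X))
  if (!is.list(svm_grid$gamma)) svm_grid$gamma <- as.list(svm_grid$gamma)
  sgrid <- expand.grid(gi = seq_along(svm_grid$gamma), C = svm_grid$C,
                       kernel = svm_grid$kernel, stringsAsFactors = FALSE)
  sres <- data.frame(C = sgrid$C,
                     gamma = vapply(svm_grid$gamma[sgrid$gi], function(g)
                       as.character(g), ""),
                     kernel = sgrid$kernel, f1 = NA_real_)
  for (i in seq_len(nrow(sgrid))) {
    sp <- modelSpec(C = sgrid$C[i], gamma = svm_grid$gamma[[sgrid$gi[i]]],
                    kernel = sgrid$kernel[i], n_estimators = 10L)
    sres$f1[i] <- cvF1(X, y, sp, "svm", nfolds, seed)
  }
  xgrid <- expand.grid(n_estimators = xgb_grid$n_estimators,
                       max_depth = xgb_grid$max_depth)
  xres <- data.frame(xgrid, f1 = NA_real_)
  for (i in seq_len(nrow(xgrid))) {
    sp <- modelSpec(n_estimators = xgrid$n_estimators[i],
                    max_depth = xgrid$max_depth[i])
    xres$f1[i] <- cvF1(X, y, sp, "xgb", nfolds, seed)
  }
  bs <- which.max(sres$f1)   # which.max takes the first maximum
  bx <- which.max(xres$f1)
  spec <- modelSpec(C = sres$C[bs], gamma = svm_grid$gamma[[sgrid$gi[bs]]],
                    kernel = sres$kernel[bs],
                    n_estimators = xres$n_estimators[bx],
                    max_depth = xres$max_depth[bx])
  list(spec = spec, svm_results = sres, xgb_results = xres)
}

#' Permutation feature importance
#'
#' Importance of feature j = baseline AUROC of the chosen ensemble member
#' minus its mean AUROC over `n_repeats` random permutations of column j.
#' Uninformative columns score near zero; the ranking is descending.
#'
#' @param object a [TREnsemble-class].
#' @param X,labels evaluation data (typically the training set).
#' @param n_repeats permutations per feature.
#' @param seed integer seed.
#' @param member `"svm"` (default, the member importance is usually
#'   reported for) or `"xgb"`.
#' @return data.frame sorted by decreasing `importance`, with columns
#'   `feature`, `importance`; attribute `baseline` holds the unpermuted
#'   AUROC.
#' @export
permutationImportance <- function(object, X, labels, n_repeats = 10L,
                                  seed = 1L, member = c("svm", "xgb")) {
  member <- match.arg(member)
  y <- normalizeLabels(labels, nrow(X))
  baseline <- rocAUC(memberScores(object, X, member), y)
  set.seed(seed)
  imp <- vapply(seq_len(ncol(X)), function(j) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      Xp <- X
      Xp[, j] <- sample(Xp[, j])
      baseline - rocAUC(memberScores(object, Xp, member), y)
    }, 0)
    mean(drops)
  }, 0)
  out <- data.frame(feature = colnames(X), importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  out
}

#' Prune highly correlated features
#'
#' Groups features whose absolute Pearson correlation exceeds
#' `r_threshold` (transitive closure: a chain of high correlations merges
#' into one group) and keeps, within each group, the member whose retention
#' yields the highest AUROC; by default that is the feature's univariate
#' AUROC against the labels (ties: first in column order). Uncorrelated
#' features always survive.
#'
#' @param X feature matrix.
#' @param labels class labels (for the default univariate-AUROC scorer).
#' @param r_threshold correlation threshold in (0, 1].
#' @param score optional named numeric vector: an externally computed
#'   AUROC-if-retained per feature, overriding the univariate default.
#' @return list: `retained` (character), `dropped`, `groups` (list of
#'   correlated groups), `score` (per-feature score used).
#' @export
correlationPrune <- function(X, labels, r_threshold = 0.9, score = NULL) {
  if (!(r_threshold > 0 && r_threshold <= 1))
    stop("r_threshold must be in (0, 1]")
  y <- normalizeLabels(labels, nrow(X))
  p <- ncol(X)
  cm <- suppressWarnings(stats::cor(X))
  cm[is.na(cm)] <- 0
  adj <- abs(cm) > r_threshold
  diag(adj) <- FALSE
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$membership
  if (is.null(score)) {
    score <- vapply(seq_len(p), function(j) rocAUC(X[, j], y), 0)
    names(score) <- colnames(X)
  }
  keep <- logical(p)
  groups <- list()
  for (g in unique(comp)) {
    members <- which(comp == g)
    best <- members[which.max(score[members])]
    keep[best] <- TRUE
    if (length(members) > 1)
      groups[[length(groups) + 1L]] <- colnames(X)[members]
  }
  list(retained = colnames(X)[keep], dropped = colnames(X)[!keep],
       groups = groups, score = score)
}

#' Save / load a fitted ensemble as a model bundle directory
#'
#' The bundle holds `meta.json` (feature schema, hyperparameters, scaler
#' constants, seed), `svm.rds` and the native `xgb.ubj` booster file.
#'
#' @param object a [TREnsemble-class].
#' @param dir bundle directory (created if needed).
#' @return `dir` / the restored [TREnsemble-class].
#' @export
saveModelBundle <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(features = object@features, spec = object@spec,
               seed = object@seed,
               scaler = list(center = as.list(object@scaler$center),
                             scale = as.list(object@scaler$scale)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(object@svm, file.path(dir, "svm.rds"))
  xgboost::xgb.save(object@xgb, file.path(dir, "xgb.ubj"))
  invisible(dir)
}

#' @rdname saveModelBundle
#' @export
loadModelBundle <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!dir.exists(dir) || !file.exists(meta_path))
    stop("model bundle not found at ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  scaler <- list(center = unlist(meta$scaler$center),
                 scale = unlist(meta$scaler$scale))
  spec <- meta$spec
  spec$features <- if (length(spec$features)) spec$features else NULL
  new("TREnsemble",
      svm = readRDS(file.path(dir, "svm.rds")),
      xgb = xgboost::xgb.load(file.path(dir, "xgb.ubj")),
      scaler = scaler, features = meta$features, spec = spec,
      seed = as.integer(meta$seed))
}
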