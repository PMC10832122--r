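#' Confusion-matrix metrics
#'
#' Accuracy (percent), precision, recall and F1 from confusion counts:
#' `accuracy = 100 * (tp + tn) / (tp + tn + fp + fn)`,
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `F1 = 2 * precision * recall / (precision + recall)`.
#' A zero denominator makes that metric `NA` (flagged as undefined, never a
#' silent zero).
#'
#' @param tp,fp,fn,tn non-negative counts. `tp` may also be a
#'   data.frame of predictions with columns `classification` and `label`
#'   (pathogenic = positive), in which case counts are derived from it.
#' @return list: `tp`, `fp`, `fn`, `tn`, `accuracy` (percent), `precision`,
#'   `recall`, `f1`.
#' @examples
#' confusionMetrics(tp = 16, fp = 1, fn = 5, tn = 82)$recall  # 0.7619
#' @export
confusionMetrics <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.data.frame(tp)) {
    df <- tp
    pos <- tolower(df$label) %in% c("pathogenic", "1", "positive")
    hit <- tolower(df$classification) %in% c("pathogenic", "1", "positive")
    tn <- sum(!pos & !hit); fp <- sum(!pos & hit)
    fn <- sum(pos & !hit); tp <- sum(pos & hit)
  }
  if (is.null(fp) || is.null(fn) || is.null(tn))
    stop("all four counts (tp, fp, fn, tn) are required")
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("empty confusion table")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = 100 * (tp + tn) / sum(counts),
       precision = precision, recall = recall, f1 = f1)
}

#' F1 from a precision/recall pair
#' @param precision,recall values in \[0, 1\] (percent inputs > 1 are
#'   divided by 100).
#' @return harmonic mean of precision and recall.
#' @export
f1Score <- function(precision, recall) {
  if (precision > 1) precision <- precision / 100
  if (recall > 1) recall <- recall / 100
  2 * precision * recall / (precision + recall)
}

#' Area under the ROC curve
#'
#' Trapezoidal rule over the ROC built from score thresholds with tied
#' scores grouped (equivalent to the Mann-Whitney statistic with average
#' ranks). Both classes must be present.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (pathogenic/1 = positive).
#' @return AUROC in \[0, 1\].
#' @export
rocAUC <- function(scores, labels) {
  y <- normalizeLabels(labels, length(scores))
  cv <- rocCurve(scores, y)
  # trapezoid over (fpr, tpr)
  sum(diff(cv$fpr) * (utils::head(cv$tpr, -1) + utils::tail(cv$tpr, -1)) / 2)
}

#' ROC curve points
#'
#' One point per distinct score threshold (ties grouped), plus the (0,0)
#' and (1,1) endpoints.
#'
#' @inheritParams rocAUC
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
rocCurve <- function(scores, labels) {
  y <- normalizeLabels(labels, length(scores))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  last <- !duplicated(s, fromLast = TRUE)   # last index of each tie group
  tp <- cumsum(y)[last]; fp <- cumsum(1 - y)[last]
  P <- sum(y); N <- length(y) - P
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp / N), tpr = c(0, tp / P))
}

#' Area under the precision-recall curve
#'
#' Step-wise (right-continuous precision) summation:
#' `sum over thresholds of (recall_i - recall_{i-1}) * precision_i`, with
#' tied scores grouped. Avoids the optimistic bias of trapezoidal
#' interpolation on PR curves.
#'
#' @inheritParams rocAUC
#' @return AUPRC in \[0, 1\].
#' @export
prAUC <- function(scores, labels) {
  cv <- prCurve(scores, labels)
  sum(diff(c(0, cv$recall)) * cv$precision)
}

#' Precision-recall curve points
#' @inheritParams rocAUC
#' @return data.frame with columns `threshold`, `recall`, `precision`.
#' @export
prCurve <- function(scores, labels) {
  y <- normalizeLabels(labels, length(scores))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  last <- !duplicated(s, fromLast = TRUE)
  tp <- cumsum(y)[last]
  pred <- which(last)                 # number predicted positive at cutoff
  P <- sum(y)
  data.frame(threshold = s[last], recall = tp / P, precision = tp / pred)
}

#' Parse an age-of-onset midpoint from printed text
#'
#' Accepted formats: `"a-b years"` (midpoint `(a+b)/2`), `"< 1 year"`
#' (0.5), a single `"a year(s)"` (the value). Purely qualitative entries
#' (e.g. `"Early"`) return `NA`, the excluded marker. Anything else is an
#' error naming the literal.
#'
#' @param text character vector of printed onset ranges.
#' @return numeric vector of midpoints in years, `NA` = excluded.
#' @examples
#' parseAgeMidpoint(c("13-60 years", "< 1 year", "Early"))
#' @export
parseAgeMidpoint <- function(text) {
  vapply(text, function(s) {
    s <- trimws(gsub("–", "-", s))   # en-dash tolerated
    if (grepl("^<\\s*[0-9.]+\\s*years?$", s)) {
      return(as.numeric(sub("^<\\s*([0-9.]+).*$", "\\1", s)) / 2)
    }
    if (grepl("^[0-9.]+\\s*-\\s*[0-9.]+\\s*years?$", s)) {
      ab <- as.numeric(strsplit(sub("\\s*years?$", "", s), "\\s*-\\s*")[[1]])
      return(mean(ab))
    }
    if (grepl("^[0-9.]+\\s*years?$", s)) {
      return(as.numeric(sub("\\s*years?$", "", s)))
    }
    if (grepl("^[A-Za-z ]+$", s)) return(NA_real_)   # qualitative: excluded
    stop("unparseable age-of-onset text: '", s, "'")
  }, 0, USE.NAMES = FALSE)
}

#' Age-of-onset vs pathogenicity-score correlation
#'
#' Spearman's rank correlation (ties by average ranks) between the midpoint
#' of each disorder's printed onset range and a per-locus pathogenicity
#' score: the maximum of the two model scores (default, matching the
#' reported score axis) or their sum (the ensemble confidence). Loci with
#' qualitative onset text are excluded.
#'
#' @param records data.frame with columns `age_of_onset`, `svm_score`,
#'   `xgb_score` (e.g. from [loadPathogenicTRs()]).
#' @param axis `"max"` or `"sum"`.
#' @return list: `rho`, `n_used`, `n_excluded`, `axis`.
#' @export
onsetCorrelation <- function(records, axis = c("max", "sum")) {
  axis <- match.arg(axis)
  mid <- parseAgeMidpoint(records$age_of_onset)
  score <- if (axis == "max") pmax(records$svm_score, records$xgb_score)
           else records$svm_score + records$xgb_score
  keep <- !is.na(mid)
  if (sum(keep) < 3) stop("need >= 3 loci with parseable onset midpoints")
  if (stats::sd(mid[keep]) == 0 || stats::sd(score[keep]) == 0)
    stop("constant vector: correlation undefined")
  list(rho = stats::cor(mid[keep], score[keep], method = "spearman"),
       n_used = sum(keep), n_excluded = sum(!keep), axis = axis)
}
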