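#' Does a locus overlap an annotation track?
#'
#' Binary overlap flag under half-open file semantics: a shared bp is an
#' overlap, a boundary touch is not (BED `[10,20)` vs `[20,30)` do not
#' overlap).
#'
#' @param locus a `GRanges`/[TRLoci-class] (any length).
#' @param track a `GRanges` annotation track.
#' @return integer vector of 0/1 flags, one per locus.
#' @export
intersectsTrack <- function(locus, track) {
  as.integer(overlapsAny(granges0(locus), granges0(track)))
}

# strip class/metadata so findOverlaps never warns about mixed seqlevels
granges0 <- function(x) {
  GRanges(as.character(seqnames(x)), IRanges(start(x), end(x)))
}

#' Interval-overlap Fisher enrichment between two tracks
#'
#' Builds a 2x2 contingency table from the merged intervals of the two
#' tracks and runs a two-sided Fisher exact test, in the spirit of
#' interval-association tests on BED files. With `a11` = merged A intervals
#' overlapping B, `a12` = merged A intervals missing B, `a21` = merged B
#' intervals missing A, the no-overlap cell is estimated as
#' `a22 = max(0, round(genome_size / slot) - a11 - a12 - a21)` where the
#' slot size is the sum of the two tracks' mean merged-interval widths
#' (the collision window of two randomly placed intervals, so that
#' independently placed tracks give odds ratios centered at 1). This
#' slot-count construction is an explicit approximation: it treats the
#' genome as a pool of collision-window-sized slots; exact parity with any
#' particular interval-statistics tool is not attempted.
#'
#' @param track_a,track_b `GRanges` tracks (non-empty).
#' @param genome_size total genome size in bp; must be at least the span
#'   covered by the merged union of both tracks.
#' @param conf.level confidence level for the odds-ratio CI.
#' @return list of class `"trEnrichment"`: `odds_ratio` (conditional-MLE),
#'   `ci_low`, `ci_high`, `p_value`, and `table` (the 2x2 matrix).
#' @seealso [fisherCI()], [compareEnrichment()]
#' @export
intervalFisher <- function(track_a, track_b, genome_size,
                           conf.level = 0.95) {
  if (!length(track_a) || !length(track_b))
    stop("both tracks must be non-empty")
  a <- reduce(granges0(track_a))
  b <- reduce(granges0(track_b))
  un <- reduce(c(a, b))
  span <- sum(as.numeric(width(un)))
  if (genome_size < span)
    stop(sprintf("genome_size (%g) smaller than covered span (%g)",
                 genome_size, span))
  n11 <- sum(overlapsAny(a, b))
  n12 <- length(a) - n11
  n21 <- sum(!overlapsAny(b, a))
  slot <- mean(width(a)) + mean(width(b))
  n22 <- max(0, round(genome_size / slot) - n11 - n12 - n21)
  tab <- matrix(c(n11, n12, n21, n22), 2, 2, byrow = TRUE,
                dimnames = list(A = c("hitB", "missB"),
                                B = c("withA", "without")))
  ft <- stats::fisher.test(tab, conf.level = conf.level)
  structure(list(odds_ratio = unname(ft$estimate),
                 ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
                 p_value = ft$p.value, table = tab,
                 conf.level = conf.level),
            class = "trEnrichment")
}

#' @export
print.trEnrichment <- function(x, ...) {
  cat(sprintf("Fisher enrichment: OR = %.4g [%.4g, %.4g] (%.0f%% CI), p = %.3g\n",
              x$odds_ratio, x$ci_low, x$ci_high, 100 * x$conf.level,
              x$p_value))
  invisible(x)
}

#' Conditional-MLE odds ratio and exact confidence interval for a 2x2 table
#'
#' The odds ratio is the conditional maximum-likelihood estimate under the
#' noncentral hypergeometric model with all margins fixed; the interval
#' bounds invert the one-sided exact tests at `(1 - level)/2` on each side.
#' Zero cells yield 0 or `Inf` bounds. The two-sided p-value sums the
#' probabilities of all tables (at fixed margins) no more probable than the
#' observed one.
#'
#' @param table 2x2 matrix or length-4 vector `(n11, n12, n21, n22)` of
#'   non-negative counts.
#' @param level confidence level in (0,1).
#' @return list: `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @examples
#' fisherCI(matrix(c(12, 2, 3, 14), 2, byrow = TRUE))
#' @export
fisherCI <- function(table, level = 0.95) {
  if (!(level > 0 && level < 1)) stop("level must be in (0,1)")
  if (is.matrix(table)) {
    tab <- matrix(as.numeric(table), 2, 2)
  } else {
    if (length(table) != 4) stop("table must be 2x2 or length 4")
    tab <- matrix(as.numeric(table), 2, 2, byrow = TRUE)
  }
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a margin is zero, odds ratio undefined")
  ft <- stats::fisher.test(tab, conf.level = level)
  list(odds_ratio = unname(ft$estimate),
       ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
       p_value = ft$p.value)
}

#' Compare two enrichment results by confidence-interval separation
#'
#' `TRUE` iff the lower CI bound of `result_a` lies strictly above the upper
#' CI bound of `result_b`, i.e. A's enrichment is significantly higher than
#' B's by non-overlapping confidence intervals.
#'
#' @param result_a,result_b lists with `ci_low`/`ci_high` (as returned by
#'   [intervalFisher()] or [fisherCI()]), computed at the same level.
#' @return logical flag.
#' @export
compareEnrichment <- function(result_a, result_b) {
  isTRUE(result_a$ci_low > result_b$ci_high)
}
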