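#' Outlier z-score of a case count against a control cohort
#'
#' Number of (sample) standard deviations the case's depth-normalized
#' anchored in-repeat-read (IRR) count lies above or below the control
#' mean. Constant controls (sd 0) yield the sentinel `Inf` when the case is
#' above the mean, `-Inf` below, 0 at the mean.
#'
#' @param case non-negative case count.
#' @param controls numeric vector of control counts (length >= 2).
#' @return the z-score.
#' @export
irrZscore <- function(case, controls) {
  if (length(controls) < 2) stop("need >= 2 controls")
  m <- mean(controls); s <- stats::sd(controls)
  if (s == 0) {
    if (case > m) return(Inf)
    if (case < m) return(-Inf)
    return(0)
  }
  (case - m) / s
}

#' Kernel-density tail probability of the control distribution
#'
#' Expected fraction of controls with counts above the case, from a
#' Gaussian kernel density over the controls:
#' `mean(pnorm((case - x_i)/h, lower.tail = FALSE))` with Silverman's
#' rule-of-thumb bandwidth `h = 0.9 * min(sd, IQR/1.34) * n^(-1/5)`
#' (floored at 1e-6). With fewer than two distinct control values the
#' empirical [irrPctAbove()] is returned instead. Monotone non-increasing
#' in `case`.
#'
#' @inheritParams irrZscore
#' @return tail probability in \[0, 1\].
#' @export
irrKdeTail <- function(case, controls) {
  if (length(unique(controls)) < 2) return(irrPctAbove(case, controls))
  n <- length(controls)
  sig <- min(stats::sd(controls), stats::IQR(controls) / 1.34)
  h <- max(0.9 * sig * n^(-1 / 5), 1e-6)
  mean(stats::pnorm((case - controls) / h, lower.tail = FALSE))
}

#' Empirical fraction of controls above the case
#'
#' Strict comparison: `#{controls > case} / n`.
#'
#' @param case case count.
#' @param controls numeric vector (length >= 1).
#' @return fraction in \[0, 1\].
#' @export
irrPctAbove <- function(case, controls) {
  if (!length(controls)) stop("need >= 1 control")
  mean(controls > case)
}

#' All three outlier statistics for one locus
#' @inheritParams irrZscore
#' @return list: `z`, `kde_tail`, `pct_above`.
#' @export
irrOutlierStats <- function(case, controls) {
  list(z = irrZscore(case, controls),
       kde_tail = irrKdeTail(case, controls),
       pct_above = irrPctAbove(case, controls))
}

#' Filter IRR records down to candidate TRs
#'
#' A record survives iff all clauses hold:
#' case IRR count >= `min_case_count` (default 5); fraction of controls
#' with an expanded allele (> 175 bp) < `max_control_freq` (default 1%);
#' region is not intergenic; the TR stems from a reference repeat locus and
#' not from an Alu element; and the locus is not blacklisted. Order is
#' preserved and every record carries its rejection reasons, so the filter
#' is idempotent on its own output.
#'
#' Reason codes: `low_irr`, `common_expansion`, `intergenic`,
#' `not_reference`, `alu_origin`, `blacklisted`.
#'
#' @param records data.frame with columns `chrom`, `start`, `end` (BED
#'   coordinates), `case_count`, `control_expanded_freq`, `region`
#'   (`exon`/`intron`/`near-gene`/`intergenic`), `from_reference_locus`,
#'   `from_alu` (logical).
#' @param blacklist optional `GRanges` (e.g. from [readBed()]) of known
#'   false-positive sites; any overlap blacklists a record.
#' @param min_case_count,max_control_freq filter thresholds.
#' @param require_reference,drop_alu set `FALSE` to disable the provenance
#'   clauses.
#' @return `records` with added columns `pass` (logical) and `reasons`
#'   (comma-separated codes, empty when passing), plus attribute
#'   `candidates` = the passing subset.
#' @export
filterCandidates <- function(records, blacklist = NULL,
                             min_case_count = 5,
                             max_control_freq = 0.01,
                             require_reference = TRUE,
                             drop_alu = TRUE) {
  n <- nrow(records)
  reasons <- vector("list", n)
  add <- function(idx, code) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], code)
  }
  add(records$case_count < min_case_count, "low_irr")
  add(records$control_expanded_freq >= max_control_freq, "common_expansion")
  add(records$region == "intergenic", "intergenic")
  if (require_reference) add(!records$from_reference_locus, "not_reference")
  if (drop_alu) add(as.logical(records$from_alu), "alu_origin")
  if (!is.null(blacklist) && length(blacklist) && n) {
    gr <- GRanges(records$chrom, IRanges(records$start + 1L, records$end))
    add(overlapsAny(gr, granges0(blacklist)), "blacklisted")
  }
  records$pass <- vapply(reasons, function(r) is.null(r), TRUE)
  records$reasons <- vapply(reasons, function(r)
    paste(r, collapse = ","), "")
  attr(records, "candidates") <- records[records$pass, , drop = FALSE]
  records
}

#' Read a dense anchored-IRR count matrix
#'
#' Tab-separated with header; metadata columns `chrom`, `start`, `end`,
#' `motif`, `region`, `from_reference_locus`, `from_alu`,
#' `control_expanded_freq`, `case`, followed by one column per control
#' sample.
#'
#' @param path input path.
#' @return list: `records` (metadata data.frame with `case_count`),
#'   `controls` (numeric matrix, loci x control samples).
#' @export
readIRRMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "")
  meta_cols <- c("chrom", "start", "end", "motif", "region",
                 "from_reference_locus", "from_alu",
                 "control_expanded_freq", "case")
  missing <- setdiff(meta_cols, colnames(df))
  if (length(missing))
    stop(path, ": missing columns: ", paste(missing, collapse = ", "))
  ctrl <- as.matrix(df[, setdiff(colnames(df), meta_cols), drop = FALSE])
  records <- df[, setdiff(meta_cols, "case")]
  records$case_count <- df$case
  list(records = records, controls = ctrl)
}

#' Run the full outlier pipeline on an IRR matrix
#'
#' Computes the three outlier statistics per locus, applies the candidate
#' filter cascade and sorts the surviving candidates by decreasing z-score
#' (high z and low tail statistics indicate a case count unlikely to come
#' from the control distribution).
#'
#' @param irr list as returned by [readIRRMatrix()] (or
#'   [simulateIRRMatrix()]).
#' @inheritParams filterCandidates
#' @return list: `records` (all loci with statistics, pass flags and
#'   reason codes) and `candidates` (passing loci sorted by z).
#' @export
outlierPipeline <- function(irr, blacklist = NULL, min_case_count = 5,
                            max_control_freq = 0.01) {
  rec <- irr$records
  st <- lapply(seq_len(nrow(rec)), function(i)
    irrOutlierStats(rec$case_count[i], irr$controls[i, ]))
  rec$z <- vapply(st, `[[`, 0, "z")
  rec$kde_tail <- vapply(st, `[[`, 0, "kde_tail")
  rec$pct_above <- vapply(st, `[[`, 0, "pct_above")
  rec <- filterCandidates(rec, blacklist = blacklist,
                          min_case_count = min_case_count,
                          max_control_freq = max_control_freq)
  cand <- rec[rec$pass, , drop = FALSE]
  cand <- cand[order(-cand$z), , drop = FALSE]
  list(records = rec, candidates = cand)
}
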