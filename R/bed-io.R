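#' Read a BED interval track
#'
#' Reads BED3+ (tab-separated, no header, 0-based half-open) into a `GRanges`
#' (1-based closed in memory). For quantitative tracks (`kind = "quantitative"`)
#' column 4 must hold a numeric value per interval, returned in metadata
#' column `value`.
#'
#' Malformed lines (fewer than 3 fields, non-integer coordinates,
#' `end <= start`, negative start) raise an error naming the line number.
#'
#' @param path path to the BED file.
#' @param name track label; defaults to the file stem.
#' @param kind `"binary"` (default) or `"quantitative"`.
#' @return `GRanges` with metadata columns `track` (the label) and, for
#'   quantitative tracks, `value`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t10\t20", "chr1\t30\t40"), bed)
#' readBed(bed)
#' @export
readBed <- function(path, name = NULL,
                    kind = c("binary", "quantitative")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track |browser )", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    gr <- GRanges()
    mcols(gr)$track <- character(0)
    if (kind == "quantitative") mcols(gr)$value <- numeric(0)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  minf <- if (kind == "quantitative") 4L else 3L
  if (any(nf < minf))
    stop(sprintf("%s: line %d has %d field(s); need >= %d",
                 path, lineno[which(nf < minf)[1]], nf[nf < minf][1], minf))
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))
  if (length(bad))
    stop(sprintf("%s: line %d: non-integer coordinates", path, lineno[bad[1]]))
  bad <- which(s < 0)
  if (length(bad))
    stop(sprintf("%s: line %d: negative start", path, lineno[bad[1]]))
  bad <- which(e <= s)
  if (length(bad))
    stop(sprintf("%s: line %d: end <= start", path, lineno[bad[1]]))
  gr <- GRanges(chrom, IRanges(s + 1, e))
  mcols(gr)$track <- name
  if (kind == "quantitative") {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("%s: line %d: non-numeric value in column 4",
                   path, lineno[bad[1]]))
    mcols(gr)$value <- v
  }
  gr
}

#' Write a GRanges as BED
#'
#' Emits tab-separated BED3 (or BED4 with metadata column `value` when
#' present), converting back to 0-based half-open coordinates.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(mcols(gr)$value)) df$value <- mcols(gr)$value
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read TR loci from a 4+ column TSV/BED
#'
#' Columns: chrom, start, end, motif, then optional gene, label, split.
#' Coordinates are 0-based half-open. A header line is detected (first line
#' whose second field is non-numeric) and skipped.
#'
#' @param path input path.
#' @return A [TRLoci-class].
#' @export
readTRLoci <- function(path) {
  if (!file.exists(path)) stop("TR file not found: ", path)
  first <- readLines(path, n = 1L)
  f1 <- strsplit(first, "\t", fixed = TRUE)[[1]]
  header <- length(f1) >= 2 && is.na(suppressWarnings(as.numeric(f1[2])))
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 4) stop(path, ": need >= 4 columns (chrom, start, end, motif)")
  nm <- c("chrom", "start", "end", "motif", "gene", "label", "split")
  colnames(df)[seq_len(min(ncol(df), 7))] <- nm[seq_len(min(ncol(df), 7))]
  TRLoci(df$chrom, df$start, df$end, df$motif,
         gene = if ("gene" %in% colnames(df)) df$gene else NA,
         label = if ("label" %in% colnames(df)) df$label else NA,
         split = if ("split" %in% colnames(df)) df$split else NA)
}

#' Write TR loci as TSV
#' @param trs a [TRLoci-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTRLoci <- function(trs, path) {
  df <- data.frame(chrom = as.character(seqnames(trs)),
                   start = start(trs) - 1L, end = end(trs),
                   motif = mcols(trs)$motif,
                   gene = mcols(trs)$gene,
                   label = mcols(trs)$label,
                   split = mcols(trs)$split)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a two-column gene-to-value table
#'
#' Tab-separated, gene symbol in column 1, numeric value in column 2 (the
#' format used for gene-level constraint scores such as pLI and LOEUF).
#'
#' @param path input path.
#' @return named numeric vector keyed by gene symbol.
#' @export
readGeneValues <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop(path, ": need 2 columns (gene, value)")
  v <- as.numeric(df[[2]])
  if (anyNA(v)) stop(path, ": non-numeric value in column 2")
  stats::setNames(v, as.character(df[[1]]))
}

#' Read a gene-to-top-tissue expression table
#'
#' Tab-separated, gene symbol in column 1, name of the tissue with maximum
#' expression in column 2.
#'
#' @param path input path.
#' @return named character vector keyed by gene symbol.
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop(path, ": need 2 columns (gene, tissue)")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write a GeneModel to a flat TSV
#'
#' One row per feature interval: symbol, chrom, start, end (0-based
#' half-open), feature in {gene, exon, utr5, utr3, promoter}, exon_index
#' (transcription order; NA for non-exons). [readGeneModel()] inverts it.
#'
#' @param gm a [GeneModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModel <- function(gm, path) {
  row <- function(gr, sym, feat, idx = NA_integer_) {
    if (!length(gr)) return(NULL)
    data.frame(symbol = sym, chrom = as.character(seqnames(gr)),
               start = start(gr) - 1L, end = end(gr),
               feature = feat, exon_index = idx)
  }
  sym <- mcols(gm@genes)$symbol
  out <- list(row(gm@genes, sym, "gene"))
  for (g in names(gm@exons)) {
    ex <- gm@exons[[g]]
    out <- c(out, list(row(ex, g, "exon", seq_along(ex))))
  }
  gsym <- function(gr) {
    s <- mcols(gr)$symbol
    if (is.null(s)) rep(NA_character_, length(gr)) else s
  }
  out <- c(out, list(row(gm@utr5, gsym(gm@utr5), "utr5"),
                     row(gm@utr3, gsym(gm@utr3), "utr3"),
                     row(gm@promoters, gsym(gm@promoters), "promoter")))
  df <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a GeneModel written by [writeGeneModel()]
#' @param path input path.
#' @return A [GeneModel-class].
#' @export
readGeneModel <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  gr <- function(d, with_symbol = TRUE) {
    g <- GRanges(d$chrom, IRanges(d$start + 1L, d$end))
    if (with_symbol) mcols(g)$symbol <- d$symbol
    g
  }
  genes <- gr(df[df$feature == "gene", ])
  exdf <- df[df$feature == "exon", ]
  exons <- GRangesList(lapply(split(exdf, exdf$symbol), function(d) {
    d <- d[order(d$exon_index), ]
    GRanges(d$chrom, IRanges(d$start + 1L, d$end))
  }))
  GeneModel(genes, exons,
            utr5 = gr(df[df$feature == "utr5", ]),
            utr3 = gr(df[df$feature == "utr3", ]),
            promoters = gr(df[df$feature == "promoter", ]))
}
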