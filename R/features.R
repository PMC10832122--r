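#' Nucleotide composition of a repeat motif
#'
#' Percentage of each base and GC content. `N` (degenerate position, e.g.
#' the polyalanine motif `GCN`) counts toward motif length but toward no
#' base, so percentages sum to 100 only for N-free motifs.
#'
#' @param motif uppercase motif over `A,C,G,T,N`.
#' @return named numeric vector `pct_A, pct_C, pct_G, pct_T, gc_pct`
#'   (each in \[0, 100\]).
#' @examples
#' motifComposition("CAG")
#' @export
motifComposition <- function(motif) {
  checkMotif(motif)
  chars <- strsplit(motif, "")[[1]]
  L <- length(chars)
  cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b), 0L)
  c(pct_A = 100 * cnt[["A"]] / L, pct_C = 100 * cnt[["C"]] / L,
    pct_G = 100 * cnt[["G"]] / L, pct_T = 100 * cnt[["T"]] / L,
    gc_pct = 100 * (cnt[["G"]] + cnt[["C"]]) / L)
}

cyclicRotations <- function(s) {
  L <- nchar(s)
  vapply(seq_len(L) - 1L, function(k)
    paste0(substr(s, k + 1L, L), substr(s, 1L, k)), "")
}

reverseComplement <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

#' Motif-class flags
#'
#' Classifies a motif against the hallmark categories of repeat-expansion
#' disorders:
#' * `disease_motif`: some cyclic rotation of the motif, or of its reverse
#'   complement, equals a catalog motif (window shifts and strand are
#'   irrelevant to which repeat a locus encodes);
#' * `pure_gc`: motif contains only G and C;
#' * `polyQ`: trinucleotide with a rotation in `{CAA, CAG}` (glutamine
#'   codons);
#' * `polyA`: trinucleotide with a rotation in `{GCA, GCC, GCG, GCT}`
#'   (alanine codons).
#'
#' @param motif uppercase motif over `A,C,G,T,N`.
#' @param disease_catalog character vector of known disease motifs
#'   (uppercase).
#' @return named logical vector
#'   `disease_motif, pure_gc, polyQ, polyA`.
#' @examples
#' motifClass("CTG", "CAG")  # reverse complement of CAG
#' @export
motifClass <- function(motif, disease_catalog = character(0)) {
  checkMotif(motif)
  rots <- unique(c(cyclicRotations(motif),
                   cyclicRotations(reverseComplement(motif))))
  c(disease_motif = any(rots %in% toupper(disease_catalog)),
    pure_gc = !grepl("[^GC]", motif),
    polyQ = nchar(motif) == 3L && any(cyclicRotations(motif) %in% c("CAA", "CAG")),
    polyA = nchar(motif) == 3L && any(cyclicRotations(motif) %in% c("GCA", "GCC", "GCG", "GCT")))
}

#' Genic context of TR loci
#'
#' For each locus: `region` is `"exon"` if the locus overlaps any exon of an
#' overlapping gene, `"intron"` if it lies within a gene span but hits no
#' exon, `"intergenic"` otherwise. `exon_position` classifies the hit exon by
#' transcription order (`"first"`, `"middle"`, `"last"`; `"none"` when the
#' region is not exonic; a single-exon gene counts as `"first"`).
#' `in_5utr` / `in_3utr` / `in_promoter` are independent overlap flags
#' against the model's UTR and promoter tracks. `gene` is the symbol of the
#' overlapping gene with the largest overlap (ties broken by
#' lexicographically smallest symbol), `NA` for intergenic loci.
#'
#' @param loci a [TRLoci-class] or `GRanges`.
#' @param genes a [GeneModel-class].
#' @return data.frame with columns `region`, `exon_position`, `in_5utr`,
#'   `in_3utr`, `in_promoter`, `gene`.
#' @export
genicContext <- function(loci, genes) {
  q <- granges0(loci)
  n <- length(q)
  sym <- mcols(genes@genes)$symbol
  gspan <- granges0(genes@genes)
  region <- rep("intergenic", n)
  exon_position <- rep("none", n)
  assigned <- rep(NA_character_, n)
  hits <- findOverlaps(q, gspan)
  if (length(hits)) {
    ov <- width(IRanges::pintersect(
      IRanges::ranges(q)[queryHits(hits)],
      IRanges::ranges(gspan)[subjectHits(hits)]))
    hdf <- data.frame(locus = queryHits(hits), gene = subjectHits(hits),
                      ov = ov, sym = sym[subjectHits(hits)])
    for (i in unique(hdf$locus)) {
      sub <- hdf[hdf$locus == i, ]
      sub <- sub[order(-sub$ov, sub$sym), ]
      assigned[i] <- sub$sym[1]
      region[i] <- "intron"
      # exon if the locus overlaps an exon of ANY overlapping gene
      for (g in sub$sym) {
        ex <- genes@exons[[g]]
        if (is.null(ex) || !length(ex)) next
        hit <- which(overlapsAny(granges0(ex), q[i]))
        if (length(hit)) {
          region[i] <- "exon"
          k <- hit[1]
          exon_position[i] <- if (k == 1L) "first"
            else if (k == length(ex)) "last" else "middle"
          break
        }
      }
    }
  }
  data.frame(region = region, exon_position = exon_position,
             in_5utr = intersectsTrack(q, genes@utr5),
             in_3utr = intersectsTrack(q, genes@utr3),
             in_promoter = intersectsTrack(q, genes@promoters),
             gene = assigned, stringsAsFactors = FALSE)
}

#' Distance from each locus to the nearest gene span
#'
#' 0 for loci overlapping a gene; otherwise the gap in bp to the closest
#' gene span on the same chromosome.
#'
#' @param loci [TRLoci-class] or `GRanges`.
#' @param genes [GeneModel-class] (non-empty).
#' @return numeric vector of distances (bp); `NA` if no gene shares the
#'   locus's chromosome.
#' @export
distanceToNearestGene <- function(loci, genes) {
  if (!length(genes@genes)) stop("gene model is empty")
  q <- granges0(loci)
  s <- granges0(genes@genes)
  hits <- distanceToNearest(q, s)
  out <- rep(NA_real_, length(q))
  out[queryHits(hits)] <- mcols(hits)$distance
  out
}

#' Tissue-expression category of a gene
#'
#' `"nervous"` if the gene's maximum-expression tissue matches the
#' configured nervous-system tissue set (substring match, e.g.
#' `"Brain - Cerebellum"` matches `"Brain"`); `"other"` if the gene is in
#' the table but its top tissue is not nervous; `"unknown"` if the gene is
#' absent or `NA` (e.g. intergenic loci).
#'
#' @param gene character vector of gene symbols (NA allowed).
#' @param expression named character vector gene -> top tissue
#'   (see [readExpressionTable()]).
#' @param nervous_tissues character vector of nervous-system tissue name
#'   patterns.
#' @return character vector in `{"nervous", "other", "unknown"}`.
#' @export
tissueCategory <- function(gene, expression,
                           nervous_tissues = c("Brain", "Nerve",
                                               "Spinal cord", "Pituitary")) {
  vapply(gene, function(g) {
    if (is.na(g) || !(g %in% names(expression))) return("unknown")
    tis <- expression[[g]]
    if (any(vapply(nervous_tissues, function(p) grepl(p, tis, fixed = TRUE), TRUE)))
      "nervous" else "other"
  }, "", USE.NAMES = FALSE)
}

#' Feature-extraction configuration
#'
#' Fixes the feature schema: which binary tracks enter (and their order),
#' the nervous-tissue set, imputation constants for missing quantitative
#' scores (neutral defaults on each score's natural scale: pLI 0, LOEUF 2
#' at the least-constrained end, GERP 0), the motif-repeat count and
#' spectral order of the topological-index block, and an optional disease
#' motif catalog (adds `disease_motif`/`pure_gc`/`polyQ`/`polyA` flags).
#'
#' @param binary_tracks character vector of binary-track names, in schema
#'   order.
#' @param nervous_tissues passed to [tissueCategory()].
#' @param impute named numeric: defaults for `pLI`, `LOEUF`, `GERP`.
#' @param motif_repeats copies of the motif for the star network.
#' @param ti_orders maximum spectral-moment order.
#' @param disease_motifs catalog for [motifClass()]; `NULL` drops the
#'   motif-class block.
#' @return list of class `"trFeatureConfig"`.
#' @export
featureConfig <- function(binary_tracks = character(0),
                          nervous_tissues = c("Brain", "Nerve",
                                              "Spinal cord", "Pituitary"),
                          impute = c(pLI = 0, LOEUF = 2, GERP = 0),
                          motif_repeats = 10L, ti_orders = 5L,
                          disease_motifs = NULL) {
  structure(list(binary_tracks = binary_tracks,
                 nervous_tissues = nervous_tissues,
                 impute = impute, motif_repeats = as.integer(motif_repeats),
                 ti_orders = as.integer(ti_orders),
                 disease_motifs = disease_motifs),
            class = "trFeatureConfig")
}

featureSchema <- function(config) {
  c(config$binary_tracks,
    paste0("region_", c("exon", "intron", "intergenic")),
    paste0("exonpos_", c("first", "middle", "last", "none")),
    "in_5utr", "in_3utr", "in_promoter",
    "pLI", "LOEUF", "GERP", "distance_to_gene",
    "pct_A", "pct_C", "pct_G", "pct_T", "gc_pct",
    if (!is.null(config$disease_motifs))
      c("disease_motif", "pure_gc", "polyQ", "polyA"),
    paste0("ti_", c("shannon_entropy", paste0("sm", seq_len(config$ti_orders)),
                    "harary", "wiener", "gutman", "schultz", "balaban",
                    "kier_hall_0", "kier_hall_1", "kier_hall_2", "randic")),
    paste0("tissue_", c("nervous", "other", "unknown")))
}

#' Assemble the model feature matrix for TR loci
#'
#' Produces the fixed, ordered numeric feature matrix the classifiers
#' consume: binary annotation-overlap flags, genic-region and exon-position
#' one-hot blocks, UTR/promoter flags, gene constraint scores (pLI, LOEUF;
#' keyed by the assigned gene), positional conservation (GERP; mean of
#' overlapping track values), distance to the nearest gene, motif base
#' percentages, optional motif-class flags, the star-network
#' topological-index block on `motif_repeats` motif copies, and the
#' tissue-category one-hot. Missing quantitative values are imputed with the
#' config constants. One-hot groups each sum to 1; the column set and order
#' are fully determined by `config` (the schema), so matrices from the same
#' config are always alignable.
#'
#' @param trs a [TRLoci-class].
#' @param binary_tracks named list of `GRanges`, one per name in
#'   `config$binary_tracks`.
#' @param quant_tracks list with optional entries `pLI`, `LOEUF` (named
#'   numeric vectors keyed by gene, see [readGeneValues()]) and `GERP`
#'   (`GRanges` with a `value` column, see [readBed()] with
#'   `kind = "quantitative"`).
#' @param genes a [GeneModel-class].
#' @param expression named character vector gene -> top tissue.
#' @param config a [featureConfig()].
#' @return numeric matrix, one row per locus (rownames
#'   `chrom:start-end:motif` in BED coordinates), columns in schema order;
#'   attribute `schema` holds the column names.
#' @export
annotateTRs <- function(trs, binary_tracks = list(), quant_tracks = list(),
                        genes, expression = character(0),
                        config = featureConfig(names(binary_tracks))) {
  missing_tracks <- setdiff(config$binary_tracks, names(binary_tracks))
  if (length(missing_tracks))
    stop("binary tracks missing from input: ",
         paste(missing_tracks, collapse = ", "))
  n <- length(trs)
  ctx <- genicContext(trs, genes)
  dist <- distanceToNearestGene(trs, genes)
  dist[is.na(dist)] <- max(dist, 0, na.rm = TRUE)
  tis <- tissueCategory(ifelse(ctx$region == "intergenic", NA, ctx$gene),
                        expression, config$nervous_tissues)
  motifs <- mcols(trs)$motif

  oneHot <- function(val, levels, prefix) {
    m <- vapply(levels, function(l) as.numeric(val == l), numeric(n))
    if (n == 1L) m <- matrix(m, nrow = 1L)
    colnames(m) <- paste0(prefix, levels)
    m
  }
  geneValue <- function(tab, default) {
    if (is.null(tab)) return(rep(default, n))
    v <- ifelse(!is.na(ctx$gene) & ctx$gene %in% names(tab),
                unname(tab[ctx$gene]), default)
    as.numeric(v)
  }
  gerp <- rep(config$impute[["GERP"]], n)
  if (!is.null(quant_tracks$GERP)) {
    gt <- quant_tracks$GERP
    hits <- findOverlaps(granges0(trs), granges0(gt))
    if (length(hits)) {
      agg <- tapply(mcols(gt)$value[subjectHits(hits)], queryHits(hits), mean)
      gerp[as.integer(names(agg))] <- as.numeric(agg)
    }
  }

  blocks <- list()
  if (length(config$binary_tracks)) {
    bm <- vapply(config$binary_tracks,
                 function(tn) as.numeric(intersectsTrack(trs, binary_tracks[[tn]])),
                 numeric(n))
    if (n == 1L) bm <- matrix(bm, nrow = 1L, dimnames = list(NULL, config$binary_tracks))
    blocks$binary <- bm
  }
  blocks$region <- oneHot(ctx$region, c("exon", "intron", "intergenic"), "region_")
  blocks$exonpos <- oneHot(ctx$exon_position, c("first", "middle", "last", "none"),
                           "exonpos_")
  blocks$flags <- cbind(in_5utr = ctx$in_5utr, in_3utr = ctx$in_3utr,
                        in_promoter = ctx$in_promoter)
  blocks$quant <- cbind(pLI = geneValue(quant_tracks$pLI, config$impute[["pLI"]]),
                        LOEUF = geneValue(quant_tracks$LOEUF, config$impute[["LOEUF"]]),
                        GERP = gerp,
                        distance_to_gene = dist)
  blocks$motif <- t(vapply(motifs, motifComposition, numeric(5)))
  if (!is.null(config$disease_motifs)) {
    blocks$motifclass <- t(vapply(motifs, function(m)
      as.numeric(motifClass(m, config$disease_motifs)), numeric(4)))
    colnames(blocks$motifclass) <- c("disease_motif", "pure_gc", "polyQ", "polyA")
  }
  ti <- t(vapply(motifs, function(m)
    motifTopologicalIndices(m, config$motif_repeats, config$ti_orders),
    numeric(10 + config$ti_orders)))
  blocks$ti <- ti
  blocks$tissue <- oneHot(tis, c("nervous", "other", "unknown"), "tissue_")

  X <- do.call(cbind, blocks)
  rownames(X) <- sprintf("%s:%d-%d:%s", as.character(seqnames(trs)),
                         start(trs) - 1L, end(trs), motifs)
  schema <- featureSchema(config)
  if (!identical(colnames(X), schema))
    stop("internal schema mismatch")   # guards against silent misalignment
  attr(X, "schema") <- schema
  X
}

#' Write/read a feature matrix as TSV
#'
#' Header row = feature names; first column `locus` = rownames.
#' @param X feature matrix from [annotateTRs()].
#' @param path file path.
#' @return `path` (write) / numeric matrix with schema attribute (read).
#' @export
writeFeatureMatrix <- function(X, path) {
  df <- data.frame(locus = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "")
  lab <- NULL
  if ("label" %in% colnames(df)) { lab <- df$label; df$label <- NULL }
  X <- as.matrix(df[, setdiff(colnames(df), "locus"), drop = FALSE])
  rownames(X) <- df$locus
  attr(X, "schema") <- colnames(X)
  if (!is.null(lab)) attr(X, "label") <- lab
  X
}
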