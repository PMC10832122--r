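#' @import methods
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   findOverlaps countOverlaps reduce distanceToNearest mcols mcols<-
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Tandem-repeat loci
#'
#' `TRLoci` extends [GenomicRanges::GRanges] with one row per tandem-repeat
#' locus. Required metadata column `motif` (uppercase over `A,C,G,T,N`;
#' `N` denotes a degenerate position, e.g. the polyalanine motif `GCN`).
#' Optional columns: `gene` (symbol), `label` (`"pathogenic"`/`"benign"`),
#' `split` (`"training"`/`"testing"`).
#'
#' Coordinates in memory follow the usual 1-based closed GRanges convention;
#' all file input/output uses 0-based half-open BED coordinates and is
#' converted at the boundary (see [readTRLoci()], [readBed()]).
#'
#' @seealso [TRLoci()] the constructor, [annotateTRs()]
#' @export
setClass("TRLoci", contains = "GRanges")

setValidity("TRLoci", function(object) {
  msg <- character()
  mc <- mcols(object)
  if (!"motif" %in% colnames(mc))
    return("TRLoci requires a 'motif' metadata column")
  motif <- as.character(mc$motif)
  if (length(object)) {
    if (anyNA(motif) || any(nchar(motif) < 1L))
      msg <- c(msg, "every locus needs a non-empty motif")
    bad <- grepl("[^ACGTN]", motif)
    if (any(bad))
      msg <- c(msg, sprintf("motif must be uppercase over {A,C,G,T,N}; offending: %s",
                            paste(unique(motif[bad]), collapse = ", ")))
  }
  if ("label" %in% colnames(mc)) {
    lab <- mc$label
    if (!all(is.na(lab) | lab %in% c("pathogenic", "benign")))
      msg <- c(msg, "label must be 'pathogenic', 'benign' or NA")
  }
  if ("split" %in% colnames(mc)) {
    sp <- mc$split
    if (!all(is.na(sp) | sp %in% c("training", "testing")))
      msg <- c(msg, "split must be 'training', 'testing' or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct TRLoci from BED-style coordinates
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open coordinates (BED convention);
#'   `end > start` required.
#' @param motif repeat unit per locus, uppercase over `A,C,G,T,N`.
#' @param gene optional gene symbol per locus.
#' @param label optional `"pathogenic"`/`"benign"`.
#' @param split optional `"training"`/`"testing"`.
#' @return A [TRLoci-class] object.
#' @examples
#' TRLoci("chr1", 100, 130, "CAG")
#' @export
TRLoci <- function(chrom, start, end, motif,
                   gene = NA_character_, label = NA_character_,
                   split = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("start must be >= 0 (0-based half-open)")
  if (any(end <= start)) stop("end must be > start (0-based half-open)")
  gr <- GRanges(chrom, IRanges(start + 1L, end),
                motif = toupper(as.character(motif)),
                gene = as.character(gene),
                label = as.character(label),
                split = as.character(split))
  new("TRLoci", gr)
}

setMethod("show", "TRLoci", function(object) {
  n <- length(object)
  lab <- mcols(object)$label
  cat(sprintf("TRLoci with %d loci (%d pathogenic, %d benign, %d unlabeled)\n",
              n, sum(lab %in% "pathogenic"), sum(lab %in% "benign"),
              sum(is.na(lab))))
  if (n) methods::callNextMethod()
})

#' Gene model for genic-context annotation
#'
#' Holds gene spans, transcription-ordered exons, UTRs and promoters as
#' `GRanges`. Exons are stored as a `GRangesList` named by gene symbol, in
#' transcription order (index 1 = first exon).
#'
#' @slot genes `GRanges` of gene spans with metadata column `symbol`.
#' @slot exons `GRangesList`, one element per gene symbol, exons in
#'   transcription order.
#' @slot utr5,utr3,promoters `GRanges`, possibly empty.
#' @seealso [GeneModel()], [genicContext()], [distanceToNearestGene()]
#' @export
setClass("GeneModel",
         representation(genes = "GRanges", exons = "GRangesList",
                        utr5 = "GRanges", utr3 = "GRanges",
                        promoters = "GRanges"))

setValidity("GeneModel", function(object) {
  msg <- character()
  sym <- mcols(object@genes)$symbol
  if (is.null(sym)) return("genes must carry a 'symbol' metadata column")
  if (anyDuplicated(sym)) msg <- c(msg, "gene symbols must be unique")
  if (!all(names(object@exons) %in% sym))
    msg <- c(msg, "exon list names must be gene symbols")
  for (g in names(object@exons)) {
    span <- object@genes[sym == g]
    ex <- object@exons[[g]]
    if (length(ex) && !all(start(ex) >= start(span) & end(ex) <= end(span)))
      msg <- c(msg, sprintf("exons of %s extend outside the gene span", g))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param genes `GRanges` of gene spans with a `symbol` metadata column.
#' @param exons named `GRangesList` (or list of `GRanges`) of exons per gene,
#'   in transcription order.
#' @param utr5,utr3,promoters optional `GRanges` tracks.
#' @return A [GeneModel-class].
#' @export
GeneModel <- function(genes, exons = NULL, utr5 = GRanges(),
                      utr3 = GRanges(), promoters = GRanges()) {
  if (is.null(exons)) exons <- GRangesList()
  if (is.list(exons) && !is(exons, "GRangesList"))
    exons <- GRangesList(exons)
  new("GeneModel", genes = genes, exons = exons, utr5 = utr5,
      utr3 = utr3, promoters = promoters)
}

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel: %d genes, %d with exon structure, %d 5'UTRs, %d 3'UTRs, %d promoters\n",
              length(object@genes), length(object@exons),
              length(object@utr5), length(object@utr3),
              length(object@promoters)))
})

#' Star-shaped sequence network
#'
#' A tree built from a character sequence: a central node plus one node per
#' sequence position. Positions sharing a symbol form a path ("ray") hanging
#' off the center, in sequence order, so the network is connected and acyclic
#' with `nchar(sequence) + 1` nodes and `nchar(sequence)` edges, one ray per
#' distinct symbol.
#'
#' @slot graph an `igraph` object (node 1 is the center).
#' @slot sequence the originating character sequence.
#' @slot rays named list mapping each symbol to the (1-based) sequence
#'   positions on its ray, in order.
#' @seealso [buildStar()], [topologicalIndices()]
#' @export
setClass("StarNetwork",
         representation(graph = "ANY", sequence = "character", rays = "list"))

setValidity("StarNetwork", function(object) {
  g <- object@graph
  L <- nchar(object@sequence)
  msg <- character()
  if (igraph::vcount(g) != L + 1L) msg <- c(msg, "node count must be length + 1")
  if (igraph::ecount(g) != L) msg <- c(msg, "edge count must equal length")
  if (!igraph::is_connected(g)) msg <- c(msg, "network must be connected")
  if (length(object@rays) != length(unique(strsplit(object@sequence, "")[[1]])))
    msg <- c(msg, "one ray per distinct symbol")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StarNetwork", function(object) {
  cat(sprintf("StarNetwork: sequence length %d, %d rays (%s)\n",
              nchar(object@sequence), length(object@rays),
              paste(names(object@rays), collapse = ",")))
})

#' Fitted SVM + XGB ensemble
#'
#' The two-member ensemble: a Platt-calibrated support vector machine fit on
#' standardized features and a gradient-boosted tree model fit on raw
#' features. A locus is called pathogenic when either member's pathogenic
#' probability exceeds 0.5; the confidence score is the sum of the two
#' probabilities (range 0-2).
#'
#' @slot svm fitted `e1071::svm` model (probability-enabled).
#' @slot xgb fitted `xgboost` booster.
#' @slot scaler list with per-feature `mean` and `sd` fitted on the training
#'   rows (population standard deviation), applied to the SVM path only.
#' @slot features character vector: the feature schema (names, in order).
#' @slot spec hyperparameter list (see [modelSpec()]).
#' @slot seed integer seed the fit was run under.
#' @seealso [trainEnsemble()], [predictScores()]
#' @export
setClass("TREnsemble",
         representation(svm = "ANY", xgb = "ANY", scaler = "list",
                        features = "character", spec = "list",
                        seed = "integer"))

setMethod("show", "TREnsemble", function(object) {
  cat(sprintf("TREnsemble: %d features; SVM(%s, C=%g) + XGB(%d rounds, depth %d); seed %d\n",
              length(object@features), object@spec$kernel, object@spec$C,
              object@spec$n_estimators, object@spec$max_depth, object@seed))
})

#' Feature schema of a fitted ensemble
#' @param object a [TREnsemble-class].
#' @return character vector of feature names in training order.
#' @export
featureNames <- function(object) object@features
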