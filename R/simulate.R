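#' Simulation configuration
#'
#' Defines the study conditions for the synthetic generators: a single
#' toy chromosome, labeled TR sets with class-controlled genic placement,
#' annotation-track overlap enrichment and nervous-tissue expression bias,
#' and a control IRR count matrix with spiked expanded cases.
#'
#' Defaults mirror the training conditions of the classifier: 40 pathogenic
#' and 745 benign loci; pathogenic loci predominantly exonic/intronic with
#' disease-type motifs, benign loci mostly non-exonic with uniform random
#' motifs; overlap and tissue probabilities chosen to echo the reported
#' class contrasts (see the methods vignette). The IRR defaults are a
#' Poisson(1) background over 500 controls with one case spiked at count
#' 20.
#'
#' @param genome_size toy chromosome length in bp.
#' @param n_pathogenic,n_benign class sizes.
#' @param region_probs per-class probabilities over
#'   `c(exon, intron, intergenic)` placement.
#' @param track_probs named list; per-track per-class probability that a
#'   locus overlaps the track.
#' @param nervous_probs per-class probability that a harboring gene's top
#'   tissue is nervous-system.
#' @param pathogenic_motifs motif pool for pathogenic loci.
#' @param irr list: `n_loci`, `n_controls`, `lambda` (Poisson background
#'   mean), `spike` (case count at spiked loci), `n_spikes`.
#' @param seed mandatory integer seed; every generator is a pure function
#'   of config + seed.
#' @return list of class `"trSimConfig"`.
#' @export
simConfig <- function(genome_size = 1e7,
                      n_pathogenic = 40L, n_benign = 745L,
                      region_probs = list(
                        pathogenic = c(exon = 0.50, intron = 0.40, intergenic = 0.10),
                        benign = c(exon = 0.03, intron = 0.47, intergenic = 0.50)),
                      track_probs = list(
                        tad_boundary = c(pathogenic = 0.30, benign = 0.05),
                        oreganno = c(pathogenic = 0.50, benign = 0.10),
                        rad21 = c(pathogenic = 0.25, benign = 0.03),
                        etr = c(pathogenic = 0.15, benign = 0.002)),
                      nervous_probs = c(pathogenic = 0.37, benign = 0.29),
                      pathogenic_motifs = c("CAG", "CGG", "GCG", "GCC", "GCN",
                                            "CTG", "GGC", "TTTCA", "GAA",
                                            "GGGGCC"),
                      irr = list(n_loci = 100L, n_controls = 500L,
                                 lambda = 1, spike = 20, n_spikes = 1L),
                      seed) {
  if (missing(seed)) stop("seed is mandatory")
  for (cls in c("pathogenic", "benign")) {
    p <- region_probs[[cls]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("region_probs$", cls, " must be a probability vector summing to 1")
  }
  structure(list(genome_size = genome_size,
                 n_pathogenic = as.integer(n_pathogenic),
                 n_benign = as.integer(n_benign),
                 region_probs = region_probs, track_probs = track_probs,
                 nervous_probs = nervous_probs,
                 pathogenic_motifs = pathogenic_motifs,
                 irr = irr, seed = as.integer(seed)),
            class = "trSimConfig")
}

randomMotif <- function() {
  paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), replace = TRUE),
        collapse = "")
}

#' Simulate a labeled TR dataset on a toy genome
#'
#' Generates a gene model (evenly spaced three-exon genes with UTRs and
#' promoters on one chromosome), places pathogenic and benign TR loci into
#' exons, introns or intergenic space according to the class-specific
#' region probabilities, draws motifs from the class pools, builds binary
#' annotation tracks whose per-class overlap frequencies converge to the
#' configured probabilities (each track also carries background intervals
#' independent of any locus), and assigns each gene a top-expression tissue
#' with the class-conditional nervous-system bias.
#'
#' Reproducible: identical config (including seed) gives byte-identical
#' output.
#'
#' @param config a [simConfig()].
#' @return list: `loci` ([TRLoci-class] with labels), `tracks` (named list
#'   of `GRanges`), `genes` ([GeneModel-class]), `expression` (named
#'   character vector gene -> top tissue).
#' @export
simulateTRDataset <- function(config) {
  stopifnot(inherits(config, "trSimConfig"))
  set.seed(config$seed)
  n_total <- config$n_pathogenic + config$n_benign
  gene_pitch <- 50000; gene_len <- 10000
  n_genes <- max(50L, min(2000L, as.integer(config$genome_size %/% gene_pitch) - 2L))
  if (n_total > config$genome_size / 1000)
    stop("infeasible config: more loci than genome slots")
  gene_start <- 100000 + (seq_len(n_genes) - 1) * gene_pitch  # 1-based
  sym <- sprintf("G%04d", seq_len(n_genes))
  genes <- GRanges("chrS", IRanges(gene_start, gene_start + gene_len - 1),
                   symbol = sym)
  exoff <- list(c(0, 999), c(4500, 5499), c(9000, 9999))
  exons <- GRangesList(stats::setNames(lapply(seq_len(n_genes), function(i)
    GRanges("chrS", IRanges(gene_start[i] + vapply(exoff, `[`, 0, 1),
                            gene_start[i] + vapply(exoff, `[`, 0, 2)))),
    sym))
  utr5 <- GRanges("chrS", IRanges(gene_start, gene_start + 299), symbol = sym)
  utr3 <- GRanges("chrS", IRanges(gene_start + gene_len - 300,
                                  gene_start + gene_len - 1), symbol = sym)
  prom <- GRanges("chrS", IRanges(pmax(1, gene_start - 1000), gene_start - 1),
                  symbol = sym)
  gm <- GeneModel(genes, exons, utr5 = utr5, utr3 = utr3, promoters = prom)

  classes <- c(rep("pathogenic", config$n_pathogenic),
               rep("benign", config$n_benign))
  motif <- character(n_total); s0 <- numeric(n_total); e0 <- numeric(n_total)
  host <- rep(NA_character_, n_total)
  for (i in seq_len(n_total)) {
    cls <- classes[i]
    motif[i] <- if (cls == "pathogenic")
      sample(config$pathogenic_motifs, 1) else randomMotif()
    w <- nchar(motif[i]) * sample(6:15, 1)
    region <- sample(c("exon", "intron", "intergenic"), 1,
                     prob = config$region_probs[[cls]])
    g <- sample(n_genes, 1)
    if (region == "exon") {
      ex <- sample(3, 1)
      pos <- gene_start[g] + exoff[[ex]][1] + sample(0:(999 - w), 1)
      host[i] <- sym[g]
    } else if (region == "intron") {
      # between exon 1 and exon 2
      pos <- gene_start[g] + 1000 + sample(0:(3500 - w - 1), 1)
      host[i] <- sym[g]
    } else {
      gap_start <- gene_start[g] + gene_len + 2000
      pos <- gap_start + sample(0:(gene_pitch - gene_len - 5000), 1)
    }
    s0[i] <- pos - 1   # back to 0-based for the constructor
    e0[i] <- s0[i] + w
  }
  loci <- TRLoci("chrS", s0, e0, motif, gene = host, label = classes)

  tracks <- list()
  for (tn in names(config$track_probs)) {
    pr <- config$track_probs[[tn]]
    hit <- stats::rbinom(n_total, 1, pr[classes]) == 1
    cover <- GRanges("chrS", IRanges(pmax(1, s0[hit] + 1 - sample(0:200, sum(hit), TRUE)),
                                     e0[hit] + sample(0:200, sum(hit), TRUE)))
    bgpos <- sort(sample(seq(1, config$genome_size - 500), 200))
    bg <- GRanges("chrS", IRanges(bgpos, bgpos + 499))
    # background intervals that would create unintended overlaps are dropped
    bg <- bg[!overlapsAny(bg, granges0(loci))]
    tracks[[tn]] <- sort(c(cover, bg))
  }

  nervous_pool <- c("Brain - Cortex", "Brain - Cerebellum", "Nerve - Tibial",
                    "Spinal cord (cervical c-1)")
  other_pool <- c("Liver", "Heart - Left Ventricle", "Muscle - Skeletal",
                  "Lung", "Whole Blood")
  expression <- stats::setNames(sample(other_pool, n_genes, TRUE), sym)
  first_class <- tapply(classes[!is.na(host)], host[!is.na(host)],
                        function(x) x[1])
  for (g in names(first_class)) {
    p <- config$nervous_probs[[first_class[[g]]]]
    expression[[g]] <- if (stats::runif(1) < p) sample(nervous_pool, 1)
                       else sample(other_pool, 1)
  }
  untouched <- setdiff(sym, names(first_class))
  nerv <- stats::runif(length(untouched)) < 0.25
  expression[untouched[nerv]] <- sample(nervous_pool, sum(nerv), TRUE)

  list(loci = loci, tracks = tracks, genes = gm, expression = expression)
}

#' Simulate an anchored-IRR count matrix with spiked expansions
#'
#' Control counts are drawn from the configured Poisson background; the
#' first `n_spikes` loci are spiked cases (genic, reference-derived, rare
#' in controls) at the configured case count, emulating a true rare
#' expansion. Background loci draw their case count from the same Poisson
#' background and carry realistic nuisance annotation: a control expansion
#' frequency up to 5%, a mix of genomic regions, and occasional Alu-derived
#' or non-reference origins.
#'
#' @param config a [simConfig()] (fields `irr` and `seed` are used).
#' @return list with `records` (metadata + `case_count`) and `controls`
#'   (matrix loci x controls), the shape returned by [readIRRMatrix()].
#' @export
simulateIRRMatrix <- function(config) {
  stopifnot(inherits(config, "trSimConfig"))
  set.seed(config$seed + 1L)
  p <- config$irr
  n <- p$n_loci
  controls <- matrix(stats::rpois(n * p$n_controls, p$lambda), nrow = n)
  colnames(controls) <- sprintf("ctrl_%03d", seq_len(p$n_controls))
  spiked <- seq_len(min(p$n_spikes, n))
  case <- stats::rpois(n, p$lambda)
  case[spiked] <- p$spike
  region <- sample(c("exon", "intron", "near-gene", "intergenic"), n, TRUE,
                   prob = c(0.1, 0.5, 0.1, 0.3))
  region[spiked] <- "intron"
  from_ref <- stats::runif(n) < 0.9; from_ref[spiked] <- TRUE
  from_alu <- stats::runif(n) < 0.1; from_alu[spiked] <- FALSE
  # background loci emulate common polymorphic repeats: expanded in >= 1%
  # of controls, so only spiked (rare) loci can pass the frequency clause
  freq <- stats::runif(n, 0.01, 0.10); freq[spiked] <- 0
  start <- sort(sample(seq(1000, config$genome_size - 1000), n))
  records <- data.frame(chrom = "chrS", start = start, end = start + 100,
                        motif = vapply(seq_len(n), function(i) randomMotif(), ""),
                        region = region, from_reference_locus = from_ref,
                        from_alu = from_alu, control_expanded_freq = freq,
                        spiked = seq_len(n) %in% spiked,
                        case_count = case)
  list(records = records, controls = controls)
}

#' Write an IRR matrix in the dense TSV layout read by [readIRRMatrix()]
#' @param irr list with `records` and `controls`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIRRMatrix <- function(irr, path) {
  rec <- irr$records
  df <- data.frame(rec[, c("chrom", "start", "end", "motif", "region",
                           "from_reference_locus", "from_alu",
                           "control_expanded_freq")],
                   case = rec$case_count, irr$controls, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

CATALOG_MD5 <- "d4c1e6a089b360bc4ac36136a0499fe1"

#' Load the packaged catalog of known pathogenic TR loci
#'
#' 61 disease-associated tandem-repeat expansion loci (40 in the training
#' split, 21 in the testing split) with, per locus: gene, disease, printed
#' age-of-onset range, motif, gene region, inheritance, whether a motif
#' change is required, whether the motif is unique among training
#' pathogenic TRs, the two published model scores and the published
#' ensemble classification. The file ships no genomic coordinates (the
#' source table prints none) and is integrity-checked by md5.
#'
#' @param path catalog TSV (defaults to the packaged file).
#' @return data.frame with 61 rows.
#' @export
loadPathogenicTRs <- function(path = system.file("extdata",
                                                 "pathogenic_tr_catalog.tsv",
                                                 package = "TRpredict")) {
  if (!nzchar(path) || !file.exists(path)) stop("catalog file not found")
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, CATALOG_MD5))
    stop("catalog checksum mismatch (", md5, "): file corrupted or modified")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  stopifnot(nrow(df) == 61)
  df
}
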