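test_that("motif composition arithmetic, including degenerate N positions", {
  expect_equal(motifComposition("CAG"),
               c(pct_A = 100 / 3, pct_C = 100 / 3, pct_G = 100 / 3,
                 pct_T = 0, gc_pct = 200 / 3))
  expect_equal(unname(motifComposition("GGGGCC")["gc_pct"]), 100)
  expect_equal(motifComposition("GCN"),
               c(pct_A = 0, pct_C = 100 / 3, pct_G = 100 / 3, pct_T = 0,
                 gc_pct = 200 / 3))
  expect_error(motifComposition(""), "non-empty")
  expect_error(motifComposition("CAX"), "outside")
  # percentages sum to 100 without N, to <= 100 with N
  for (m in c("A", "CAG", "TTTCA", "GGGGCC")) {
    expect_equal(sum(motifComposition(m)[1:4]), 100)
  }
  expect_lt(sum(motifComposition("GCN")[1:4]), 100)
})

test_that("motif classes respect rotation and reverse complement", {
  expect_true(motifClass("AGC", "CAG")[["disease_motif"]])
  expect_true(motifClass("CTG", "CAG")[["disease_motif"]])
  expect_false(motifClass("AAG", "CAG")[["disease_motif"]])
  gg <- motifClass("GGC")
  expect_true(gg[["pure_gc"]])
  expect_true(gg[["polyA"]])    # rotation GCG is an alanine codon
  expect_false(gg[["polyQ"]])
  expect_true(motifClass("ACA")[["polyQ"]])  # rotation CAA
  expect_false(motifClass("TTTCA")[["polyQ"]])
  # invariance of the disease flag under rotation and reverse complement
  catalog <- c("CAG", "TTTCA", "GGGGCC")
  rot <- function(s, k) paste0(substr(s, k + 1, nchar(s)), substr(s, 1, k))
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  for (m in catalog) {
    for (k in 0:(nchar(m) - 1)) {
      expect_true(motifClass(rot(m, k), catalog)[["disease_motif"]])
      expect_true(motifClass(rc(rot(m, k)), catalog)[["disease_motif"]])
    }
  }
})

test_that("genic context distinguishes exon, intron and intergenic loci", {
  gm <- toyGeneModel()
  # inside exon 1 (also the 5'UTR head of the gene)
  ctx <- genicContext(TRLoci("chrT", 1050, 1080, "CAG"), gm)
  expect_equal(ctx$region, "exon")
  expect_equal(ctx$exon_position, "first")
  expect_equal(ctx$in_5utr, 1L)
  expect_equal(ctx$gene, "geneA")
  # between exon 1 and exon 2
  ctx <- genicContext(TRLoci("chrT", 1500, 1530, "CAG"), gm)
  expect_equal(ctx$region, "intron")
  expect_equal(ctx$exon_position, "none")
  # middle and last exons
  expect_equal(genicContext(TRLoci("chrT", 2100, 2120, "CAG"), gm)$exon_position,
               "middle")
  expect_equal(genicContext(TRLoci("chrT", 3600, 3620, "CAG"), gm)$exon_position,
               "last")
  # far away
  ctx <- genicContext(TRLoci("chrT", 14000, 14030, "CAG"), gm)
  expect_equal(ctx$region, "intergenic")
  expect_equal(ctx$exon_position, "none")
  expect_true(is.na(ctx$gene))
  # promoter flag is an independent overlap test
  expect_equal(genicContext(TRLoci("chrT", 600, 630, "CAG"), gm)$in_promoter, 1L)
})

test_that("distance to the nearest gene is a half-open gap", {
  gm <- toyGeneModel()
  expect_equal(distanceToNearestGene(TRLoci("chrT", 1500, 1530, "CAG"), gm), 0)
  # locus [100,110) vs gene starting at base 1000 (0-based): gap 890
  expect_equal(distanceToNearestGene(TRLoci("chrT", 100, 110, "CAG"), gm), 890)
  expect_equal(distanceToNearestGene(TRLoci("chrT", 4100, 4110, "CAG"), gm), 100)
  expect_error(distanceToNearestGene(TRLoci("chrT", 1, 10, "CAG"),
                                     GeneModel(GenomicRanges::GRanges(
                                       symbol = character(0)))),
               "empty")
})

test_that("tissue category follows the configured nervous-system set", {
  expr <- c(geneA = "Brain - Cerebellum", geneB = "Liver",
            geneC = "Nerve - Tibial")
  expect_equal(tissueCategory(c("geneA", "geneB", "geneC", "geneZ", NA), expr),
               c("nervous", "other", "nervous", "unknown", "unknown"))
  # custom set
  expect_equal(tissueCategory("geneB", expr, nervous_tissues = "Liver"),
               "nervous")
})

test_that("feature assembly is deterministic with fixed schema and one-hot blocks", {
  gm <- toyGeneModel()
  tracks <- list(tad = grTrack(1000, 1200), etr = grTrack(9000, 9100))
  expr <- c(geneA = "Brain - Cortex")
  quant <- list(pLI = c(geneA = 0.98), LOEUF = c(geneA = 0.2),
                GERP = {
                  g <- grTrack(1000, 1300)
                  GenomicRanges::mcols(g)$value <- 2.5
                  g
                })
  trs <- TRLoci("chrT", c(1050, 1500, 14000), c(1080, 1530, 14030),
                c("CAG", "TTTCA", "GCN"))
  cfg <- featureConfig(names(tracks))
  X1 <- annotateTRs(trs, tracks, quant, gm, expr, cfg)
  X2 <- annotateTRs(trs, tracks, quant, gm, expr, cfg)
  expect_identical(X1, X2)
  expect_identical(colnames(X1), attr(X1, "schema"))

  expect_equal(unname(X1[, "tad"]), c(1, 0, 0))
  expect_equal(rowSums(X1[, c("region_exon", "region_intron", "region_intergenic")]),
               stats::setNames(rep(1, 3), rownames(X1)))
  expect_equal(rowSums(X1[, paste0("exonpos_", c("first", "middle", "last", "none"))]),
               stats::setNames(rep(1, 3), rownames(X1)))
  expect_equal(rowSums(X1[, paste0("tissue_", c("nervous", "other", "unknown"))]),
               stats::setNames(rep(1, 3), rownames(X1)))
  # 5'UTR flag delegates to interval overlap (locus 1 sits in the UTR head)
  expect_equal(unname(X1[, "in_5utr"]), c(1, 0, 0))
  # exon-position one-hot is "none" whenever the region is not exon
  nonexon <- X1[, "region_exon"] == 0
  expect_true(all(X1[nonexon, "exonpos_none"] == 1))
  # gene-keyed scores resolve through the assigned gene; imputed elsewhere
  expect_equal(unname(X1[, "pLI"]), c(0.98, 0.98, 0))
  expect_equal(unname(X1[, "LOEUF"]), c(0.2, 0.2, 2))
  expect_equal(unname(X1[, "GERP"]), c(2.5, 0, 0))
  # intergenic locus: unknown tissue, positive gene distance
  expect_equal(unname(X1[14000 == GenomicRanges::start(trs) - 1, "tissue_unknown"]), 1)
  expect_gt(X1[3, "distance_to_gene"], 0)
})

test_that("feature assembly refuses missing tracks", {
  gm <- toyGeneModel()
  trs <- TRLoci("chrT", 1050, 1080, "CAG")
  cfg <- featureConfig(c("tad", "absent_track"))
  expect_error(annotateTRs(trs, list(tad = grTrack(0, 10)), list(), gm,
                           character(0), cfg),
               "absent_track")
})

test_that("TRLoci validity enforces motif alphabet and label vocabulary", {
  expect_error(TRLoci("chr1", 10, 10, "CAG"), "end must be > start")
  expect_error(TRLoci("chr1", -1, 10, "CAG"), "start")
  expect_error(TRLoci("chr1", 0, 10, "CAQ"), "motif")
  tr <- TRLoci("chr1", 0, 10, "cag")   # constructor uppercases
  expect_equal(GenomicRanges::mcols(tr)$motif, "CAG")
})
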