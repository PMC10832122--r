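test_that("generators are pure functions of config and seed", {
  cfg <- simConfig(seed = 17, n_pathogenic = 20, n_benign = 40)
  a <- simulateTRDataset(cfg)
  b <- simulateTRDataset(cfg)
  expect_identical(a, b)
  ia <- simulateIRRMatrix(cfg)
  ib <- simulateIRRMatrix(cfg)
  expect_identical(ia, ib)
  c2 <- simulateTRDataset(simConfig(seed = 18, n_pathogenic = 20, n_benign = 40))
  expect_false(identical(a$loci, c2$loci))
  expect_error(simConfig(n_pathogenic = 10), "seed")
  expect_error(simulateTRDataset(simConfig(seed = 1, genome_size = 1e4,
                                           n_pathogenic = 50, n_benign = 50)),
               "infeasible")
})

test_that("realized overlap frequencies track the configured enrichment", {
  cfg <- simConfig(seed = 23, n_pathogenic = 200, n_benign = 200,
                   track_probs = list(tad_boundary = c(pathogenic = 0.6,
                                                       benign = 0.1)))
  sim <- simulateTRDataset(cfg)
  lab <- GenomicRanges::mcols(sim$loci)$label
  hit <- intersectsTrack(sim$loci, sim$tracks$tad_boundary)
  expect_equal(mean(hit[lab == "pathogenic"]), 0.6, tolerance = 0.1)
  expect_lte(mean(hit[lab == "benign"]), 0.25)
})

test_that("planted exon enrichment is recovered by the Fisher module", {
  cfg <- simConfig(seed = 29, n_pathogenic = 500, n_benign = 500,
                   region_probs = list(
                     pathogenic = c(exon = 0.8, intron = 0.15, intergenic = 0.05),
                     benign = c(exon = 0.05, intron = 0.45, intergenic = 0.50)))
  sim <- simulateTRDataset(cfg)
  lab <- GenomicRanges::mcols(sim$loci)$label
  exons <- unlist(sim$genes@exons)
  res <- intervalFisher(sim$loci[lab == "pathogenic"], exons,
                        genome_size = cfg$genome_size)
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p_value, 0.01)
})

test_that("simulated IRR matrices respect the spike contract", {
  cfg <- simConfig(seed = 31)
  irr <- simulateIRRMatrix(cfg)
  out <- outlierPipeline(irr)
  expect_true(all(out$candidates$spiked))
  expect_equal(nrow(out$candidates), 1)
  # zero spikes, default thresholds: no candidates by construction
  cfg0 <- simConfig(seed = 31, irr = list(n_loci = 100, n_controls = 500,
                                          lambda = 1, spike = 20, n_spikes = 0))
  out0 <- outlierPipeline(simulateIRRMatrix(cfg0))
  expect_equal(nrow(out0$candidates), 0)
  # round trip through the dense TSV layout
  path <- withr::local_tempfile(fileext = ".tsv")
  writeIRRMatrix(irr, path)
  back <- readIRRMatrix(path)
  expect_equal(back$records$case_count, irr$records$case_count)
  expect_equal(unname(back$controls), unname(irr$controls))
})

test_that("flat enrichment yields chance-level LOOCV on annotation flags alone", {
  # LOOCV at this n has a known pessimistic (anti-learning) spread under the
  # null, so the chance-level check is on the mean over generator seeds
  aucs <- vapply(37:39, function(s) {
    flat <- simConfig(seed = s, n_pathogenic = 60, n_benign = 60,
                      region_probs = list(
                        pathogenic = c(exon = 0.2, intron = 0.4, intergenic = 0.4),
                        benign = c(exon = 0.2, intron = 0.4, intergenic = 0.4)),
                      track_probs = list(tad_boundary = c(pathogenic = 0.2,
                                                          benign = 0.2),
                                         oreganno = c(pathogenic = 0.3,
                                                      benign = 0.3)),
                      nervous_probs = c(pathogenic = 0.3, benign = 0.3))
    sim <- simulateTRDataset(flat)
    lab <- GenomicRanges::mcols(sim$loci)$label
    cfg <- featureConfig(names(sim$tracks))
    X <- annotateTRs(sim$loci, sim$tracks, list(), sim$genes, sim$expression, cfg)
    # annotation flags only: strip motif-derived blocks, which still differ
    # between the class-specific motif pools
    keep <- c(names(sim$tracks), "region_exon", "region_intron",
              "region_intergenic", "in_5utr", "in_3utr", "in_promoter",
              "tissue_nervous", "tissue_other", "tissue_unknown")
    cv <- loocvEnsemble(X[, keep], lab, seed = 3)
    rocAUC(cv$confidence, lab == "pathogenic")
  }, 0)
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("the packaged pathogenic-TR catalog is intact and self-consistent", {
  t1 <- loadPathogenicTRs()
  expect_equal(nrow(t1), 61)
  expect_equal(sum(t1$dataset == "Training"), 40)
  expect_equal(sum(t1$dataset == "Testing"), 21)
  samd12 <- t1[t1$gene == "SAMD12", ]
  expect_equal(samd12$svm_score, 0.94)
  expect_equal(samd12$xgb_score, 0)
  expect_equal(samd12$classification, "Pathogenic")
  expect_equal(samd12$dataset, "Training")
  # score pairs reproduce the shipped classification column
  r <- ensembleClassify(t1$svm_score, t1$xgb_score)
  expect_equal(r$classification, t1$classification)
  # tampering is detected by the checksum
  orig <- system.file("extdata", "pathogenic_tr_catalog.tsv",
                      package = "TRpredict")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sub("0.94", "0.95", readLines(orig)), tmp)
  expect_error(loadPathogenicTRs(tmp), "checksum")
})
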