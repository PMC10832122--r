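# Independent brute-force oracles, kept free of the code paths they check.

# Two-sided Fisher p by full enumeration of the hypergeometric support at
# fixed margins: sum probabilities of all tables no more probable than the
# observed one (with a tiny relative tolerance for float ties).
bruteFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(support, r1, r2, c1)
  pobs <- dhyper(a, r1, r2, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Conditional-MLE odds ratio by direct likelihood maximization under the
# noncentral hypergeometric model (log-scale golden-section via optimize).
bruteCondMLE <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  if (a == min(support)) return(0)
  if (a == max(support)) return(Inf)
  logw <- lchoose(r1, support) + lchoose(r2, c1 - support)
  negll <- function(logpsi) {
    lp <- logw + support * logpsi
    -(logw[support == a] + a * logpsi - matrixStats_logSumExp(lp))
  }
  exp(stats::optimize(negll, c(-25, 25), tol = 1e-10)$minimum)
}

matrixStats_logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# All-pairs shortest-path distances by Floyd-Warshall on an edge list
# (1-based node ids), independent of igraph.
bruteDistances <- function(edges, n) {
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    D[i, j] <- 1; D[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    nd <- D[i, k] + D[k, ]
    upd <- nd < D[i, ]
    D[i, upd] <- nd[upd]
  }
  D
}

# Index set computed straight from a distance matrix + degree sequence;
# written independently of topologicalIndices().
bruteIndices <- function(edges, n) {
  D <- bruteDistances(edges, n)
  deg <- tabulate(as.vector(edges), n)
  ut <- upper.tri(D)
  m <- nrow(edges)
  s <- rowSums(D)
  list(wiener = sum(D[ut]),
       harary = sum(1 / D[ut]),
       gutman = sum((outer(deg, deg) * D)[ut]),
       schultz = sum((outer(deg, deg, `+`) * D)[ut]),
       balaban = (m / (m - n + 1 + 1)) *
         sum(1 / sqrt(s[edges[, 1]] * s[edges[, 2]])),
       randic = sum(1 / sqrt(deg[edges[, 1]] * deg[edges[, 2]])))
}

# Random labeled tree on n nodes via a random Prufer sequence.
randomTreeEdges <- function(n) {
  if (n == 2) return(matrix(c(1, 2), 1))
  prufer <- sample(n, n - 2, replace = TRUE)
  degree <- rep(1L, n) + tabulate(prufer, n)
  edges <- matrix(0L, n - 1, 2)
  ptr <- 0L
  for (k in seq_len(n - 2)) {
    leaf <- min(which(degree == 1L))
    edges[k, ] <- c(leaf, prufer[k])
    degree[leaf] <- 0L
    degree[prufer[k]] <- degree[prufer[k]] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

# Linearly separable two-class dataset with planted informative features.
makeSeparable <- function(n = 60, p_noise = 3, delta = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), length.out = n)
  X <- cbind(inf1 = rnorm(n, delta * y, 0.5),
             inf2 = rnorm(n, -delta * y, 0.5),
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  list(X = X, y = y)
}

# Minimal hand-built gene model on a toy chromosome:
# geneA [1000, 4000) with exons [1000,1300), [2000,2300), [3500,4000);
# 5'UTR [1000,1100), 3'UTR [3900,4000), promoter [500,1000). All 1-based
# closed internally (constructed directly as GRanges).
toyGeneModel <- function() {
  genes <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1001, 4000),
                                  symbol = "geneA")
  exons <- GenomicRanges::GRangesList(geneA = GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(1001, 2001, 3501), c(1300, 2300, 4000))))
  GeneModel(genes, exons,
            utr5 = GenomicRanges::GRanges("chrT", IRanges::IRanges(1001, 1100)),
            utr3 = GenomicRanges::GRanges("chrT", IRanges::IRanges(3901, 4000)),
            promoters = GenomicRanges::GRanges("chrT", IRanges::IRanges(501, 1000)))
}

grTrack <- function(start0, end0, chrom = "chrT") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
}
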