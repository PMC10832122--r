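#' Build a star-shaped network from a sequence
#'
#' One central node plus one node per sequence position. All positions
#' carrying the same symbol form a path (a "ray") off the center, appended
#' in sequence order: the first occurrence of a symbol attaches to the
#' center, each later occurrence to the previous occurrence of that symbol.
#' The result is a tree with `L + 1` nodes and `L` edges (`L` = sequence
#' length) and one ray per distinct symbol.
#'
#' @param seq non-empty character sequence (any finite alphabet).
#' @return A [StarNetwork-class].
#' @examples
#' buildStar("ACG")    # star K(1,3)
#' buildStar(strrep("CAG", 10))
#' @export
buildStar <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("seq must be a single non-empty string")
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  rays <- split(seq_len(L), chars)
  rays <- rays[unique(chars)]           # rays in order of first appearance
  # node 1 = center, node i+1 = position i
  last <- integer(0)
  from <- integer(L); to <- integer(L)
  for (i in seq_len(L)) {
    s <- chars[i]
    from[i] <- if (s %in% names(last)) last[[s]] + 1L else 1L
    to[i] <- i + 1L
    last[[s]] <- i
  }
  g <- igraph::make_empty_graph(n = L + 1L, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  new("StarNetwork", graph = g, sequence = seq, rays = as.list(rays))
}

#' Topological indices of a star network (or any connected graph)
#'
#' Computes the descriptor block used as motif features: Shannon entropy of
#' the degree distribution, spectral moments (traces of adjacency powers,
#' orders `1..K`), Harary and Wiener distance indices, Gutman and Schultz
#' degree-distance indices, the Balaban distance-connectivity index J,
#' Kier-Hall chi connectivity of orders 0-2 (order 1 equals the Randic
#' index), and the Randic index.
#'
#' Definitions, with `D` the unweighted shortest-path distance matrix,
#' `deg` the degree sequence, `m` edges, `n` nodes:
#' * `shannon_entropy = -sum(p * log(p))`, `p = deg / sum(deg)` (nats)
#' * `smK = trace(A^K)`
#' * `wiener = sum_{i<j} D_ij`; `harary = sum_{i<j} 1/D_ij`
#' * `gutman = sum_{i<j} deg_i deg_j D_ij`;
#'   `schultz = sum_{i<j} (deg_i + deg_j) D_ij`
#' * `balaban = m/(mu+1) * sum_edges (s_i s_j)^(-1/2)` with `s_i = sum_j D_ij`
#'   and `mu = m - n + 1` the cyclomatic number (0 for trees)
#' * `kier_hall_0 = sum_i deg_i^(-1/2)`;
#'   `kier_hall_1 = randic = sum_edges (deg_i deg_j)^(-1/2)`;
#'   `kier_hall_2 = sum over 2-paths i-j-k of (deg_i deg_j deg_k)^(-1/2)`
#'
#' @param g a [StarNetwork-class] or a connected `igraph` graph.
#' @param K maximum spectral-moment order (default 5).
#' @return named numeric vector:
#'   `shannon_entropy, sm1..smK, harary, wiener, gutman, schultz, balaban,
#'    kier_hall_0, kier_hall_1, kier_hall_2, randic`.
#' @examples
#' topologicalIndices(buildStar("ACG"))["wiener"]  # 9 for K(1,3)
#' @export
topologicalIndices <- function(g, K = 5L) {
  if (is(g, "StarNetwork")) g <- g@graph
  if (!igraph::is_igraph(g)) stop("g must be a StarNetwork or igraph graph")
  if (!igraph::is_connected(g)) stop("graph must be connected")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  n <- nrow(A)
  deg <- rowSums(A)
  m <- sum(deg) / 2
  D <- igraph::distances(g)
  ut <- upper.tri(D)

  p <- deg / sum(deg)
  entropy <- -sum(p[p > 0] * log(p[p > 0]))

  sm <- numeric(K)
  P <- A
  for (k in seq_len(K)) {
    sm[k] <- sum(diag(P))
    if (k < K) P <- P %*% A
  }

  wiener <- sum(D[ut])
  harary <- sum(1 / D[ut])
  degprod <- outer(deg, deg)
  degsum <- outer(deg, deg, `+`)
  gutman <- sum((degprod * D)[ut])
  schultz <- sum((degsum * D)[ut])

  el <- igraph::as_edgelist(g, names = FALSE)
  s <- rowSums(D)
  mu <- m - n + 1
  balaban <- (m / (mu + 1)) * sum(1 / sqrt(s[el[, 1]] * s[el[, 2]]))

  kh0 <- sum(deg^(-0.5))
  randic <- sum(1 / sqrt(deg[el[, 1]] * deg[el[, 2]]))
  # 2-paths: for each middle node j, unordered pairs of distinct neighbors
  kh2 <- 0
  adj <- igraph::as_adj_list(g)
  for (j in seq_len(n)) {
    nb <- as.integer(adj[[j]])
    if (length(nb) >= 2) {
      w <- 1 / sqrt(deg[nb])
      sw <- sum(w)
      kh2 <- kh2 + deg[j]^(-0.5) * (sw^2 - sum(w^2)) / 2
    }
  }
  out <- c(shannon_entropy = entropy,
           stats::setNames(sm, paste0("sm", seq_len(K))),
           harary = harary, wiener = wiener, gutman = gutman,
           schultz = schultz, balaban = balaban,
           kier_hall_0 = kh0, kier_hall_1 = randic, kier_hall_2 = kh2,
           randic = randic)
  out
}

#' Topological-index block for a repeat motif
#'
#' Builds the star network of `repeats` concatenated copies of the motif
#' (default 10, the convention used when featurizing TR motifs) and returns
#' its topological indices with names prefixed `ti_`.
#'
#' @param motif uppercase motif over `A,C,G,T,N`.
#' @param repeats number of concatenated motif copies.
#' @param K maximum spectral-moment order.
#' @return named numeric vector (see [topologicalIndices()]).
#' @export
motifTopologicalIndices <- function(motif, repeats = 10L, K = 5L) {
  checkMotif(motif)
  ti <- topologicalIndices(buildStar(strrep(motif, repeats)), K = K)
  stats::setNames(ti, paste0("ti_", names(ti)))
}

checkMotif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    stop("motif must be a single non-empty string")
  if (grepl("[^ACGTN]", motif))
    stop("motif contains characters outside {A,C,G,T,N}: ", motif)
  invisible(motif)
}
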