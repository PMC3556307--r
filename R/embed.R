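#' k-mer composition profiles
#'
#' Counts all forward-strand k-mer windows of each sequence (windows
#' containing a non-ACGT letter are skipped) and normalizes each profile to
#' sum to 1. Sequences with no valid window get a zero profile with a
#' warning.
#'
#' @param seqs Named `DNAStringSet` or character vector.
#' @param k Word length (default 5, the feature set used for embedding).
#' @return Numeric matrix, one row per sequence, `4^k` columns.
#' @export
kmer_profile <- function(seqs, k = 5L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (any(Biostrings::width(seqs) < k))
    stop("all sequences must be at least k bases long")
  cnt <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  tot <- rowSums(cnt)
  if (any(tot == 0))
    warning("sequence(s) with no valid k-mer window; zero profile returned")
  prof <- cnt / pmax(tot, 1)
  rownames(prof) <- names(seqs)
  prof
}

# Minimum spanning tree by Kruskal on a full distance matrix.
# Edge ties broken lexicographically by (weight, i, j) for determinism.
# Returns a data.frame (i, j, w) with n-1 rows.
mst_kruskal <- function(D) {
  n <- nrow(D)
  if (n < 2) return(data.frame(i = integer(), j = integer(), w = double()))
  idx <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[upper.tri(D)], idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  out <- list()
  for (r in seq_len(nrow(idx))) {
    a <- find(idx[r, 1]); b <- find(idx[r, 2])
    if (a != b) {
      parent[a] <- b
      out[[length(out) + 1L]] <- c(idx[r, 1], idx[r, 2],
                                   D[idx[r, 1], idx[r, 2]])
      if (length(out) == n - 1L) break
    }
  }
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), w = m[, 3])
}

# Geodesic (path) distances between all nodes along tree edges.
tree_geodesic <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]; w <- edges$w[r]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  G <- matrix(0, n, n)
  for (s in seq_len(n)) {      # BFS from each node; tree => unique paths
    dist <- rep(NA_real_, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- adj[[u]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        if (is.na(dist[v])) {
          dist[v] <- dist[u] + nb[r, 2]
          queue <- c(queue, v)
        }
      }
    }
    G[s, ] <- dist
  }
  G
}

#' Non-centered minimum curvilinear embedding (MCE)
#'
#' Embeds samples by the minimum curvilinear kernel: (1) pairwise Euclidean
#' distances over the profiles; (2) minimum spanning tree (MST) of that
#' distance graph; (3) kernel = matrix of pairwise geodesic distances along
#' MST edges (the "minimum curvilinear" distance); (4) singular value
#' decomposition of the kernel *without* row/column centering; (5)
#' coordinates = top-`d` left singular vectors scaled by the square roots of
#' their singular values. Following nonlinear paths through the MST instead
#' of straight-line distances lets elongated, low-density structures
#' separate in few dimensions.
#'
#' Sign convention: each coordinate axis is flipped so its largest-magnitude
#' loading is positive, making the output deterministic.
#'
#' @param profiles Numeric matrix (samples x features), e.g. from
#'   [kmer_profile()].
#' @param d Number of embedding dimensions (default 3; `d <=` sample count).
#' @return List with `coords` (samples x d), `singular_values`
#'   (nonincreasing), `kernel` (the MST-geodesic distance matrix) and
#'   `mst` (edge data.frame `i`,`j`,`w`).
#' @export
mce_embed <- function(profiles, d = 3L) {
  n <- nrow(profiles)
  if (is.null(n) || n < 2) stop("need at least 2 profiles")
  if (d > n) stop("d cannot exceed the number of samples")
  D <- as.matrix(stats::dist(profiles))
  edges <- mst_kruskal(D)
  K <- tree_geodesic(n, edges)
  sv <- svd(K, nu = d, nv = 0)
  coords <- sv$u %*% diag(sqrt(sv$d[seq_len(d)]), d, d)
  for (c in seq_len(d)) {
    m <- which.max(abs(coords[, c]))
    if (coords[m, c] < 0) coords[, c] <- -coords[, c]
  }
  rownames(coords) <- rownames(profiles)
  colnames(coords) <- paste0("dim", seq_len(d))
  rownames(K) <- colnames(K) <- rownames(profiles)
  list(coords = coords, singular_values = sv$d, kernel = K, mst = edges)
}
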