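#' Markov clustering (MCL) of a weighted graph
#'
#' Clusters a weighted undirected graph by alternating *expansion* (matrix
#' squaring of the column-stochastic transition matrix, i.e. two-step random
#' walk) and *inflation* (entrywise powering followed by column
#' renormalization), iterated to a fixpoint. Defaults follow the standard
#' MCL parameterization: inflation 2.0, self-loop weight equal to the
#' maximum incident edge weight (1 for isolated nodes), entries below
#' `prune` dropped each iteration, convergence when the largest entry
#' change falls below `tol`.
#'
#' Clusters are read from the converged matrix as the connected components
#' of its support, which assigns every node to exactly one cluster; clusters
#' are numbered 1, 2, ... by their lowest node index, so ties and labels are
#' deterministic.
#'
#' @param graph A list with `nodes` and `edges` as returned by
#'   [build_graph()], or a symmetric numeric adjacency matrix.
#' @param inflation Inflation exponent (> 1).
#' @param prune Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap; non-convergence raises a warning and the
#'   current interpretation is returned.
#' @param tol Convergence threshold on the max entry change.
#' @return data.frame (`id`, `cluster`), clusters numbered from 1.
#' @export
mcl <- function(graph, inflation = 2.0, prune = 1e-5, max_iter = 200L,
                tol = 1e-6) {
  if (is.matrix(graph)) {
    A <- graph
    ids <- rownames(A)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(A)))
  } else {
    ids <- graph$nodes
    n <- length(ids)
    A <- matrix(0, n, n, dimnames = list(ids, ids))
    e <- graph$edges
    if (nrow(e)) {
      for (r in seq_len(nrow(e))) {
        A[e$from[r], e$to[r]] <- e$score_density[r]
        A[e$to[r], e$from[r]] <- e$score_density[r]
      }
    }
  }
  if (nrow(A) == 0) stop("empty graph")
  if (any(A < 0)) stop("edge weights must be non-negative")
  n <- nrow(A)
  diag(A) <- 0
  loops <- apply(A, 2, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                   # expansion
    M2 <- M2^inflation              # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged)
    warning("MCL did not converge within max_iter; returning current state")
  sup <- (M > 0) | (t(M) > 0)
  comp <- integer(n)                # connected components of the support
  cl <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    cl <- cl + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (comp[u] > 0L) next
      comp[u] <- cl
      queue <- c(queue, which(sup[u, ] & comp == 0L))
    }
  }
  data.frame(id = ids, cluster = comp, stringsAsFactors = FALSE)
}

#' Species composition of clusters
#'
#' @param clusters Cluster table from [mcl()] over UCR ids.
#' @param ucrs UCR table (provides `ucr_id` -> `species`).
#' @return data.frame (`cluster`, `species`, `n`).
#' @export
cluster_composition <- function(clusters, ucrs) {
  sp <- ucrs$species[match(clusters$id, ucrs$ucr_id)]
  agg <- stats::aggregate(list(n = clusters$id),
                          by = list(cluster = clusters$cluster, species = sp),
                          FUN = length)
  agg[order(agg$cluster, agg$species), ]
}
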