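#' @useDynLib ultracons, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Build the rate-normalized JTT model: instantaneous rate matrix Q with
# equilibrium frequencies pi, scaled to one expected substitution per site,
# plus the symmetric eigendecomposition used to evaluate P(t) = exp(Qt).
# Exchangeabilities and frequencies come from phangorn's published model
# table (lower-triangle order matches the AA20 alphabet above).
jtt_model <- function() {
  mdl <- get(".JTT", asNamespace("phangorn"))
  S <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  S[lower.tri(S)] <- mdl$Q
  S <- S + t(S)
  pi <- as.numeric(mdl$bf)
  names(pi) <- AA20
  pi <- pi / sum(pi)
  Q <- S * rep(pi, each = 20)     # Q_ij = S_ij * pi_j
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q <- Q / rate
  # symmetrized eigendecomposition: B = D^(1/2) Q D^(-1/2) is symmetric
  rs <- sqrt(pi)
  B <- Q * (rs %o% (1 / rs))
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(Q = Q, pi = pi, values = eig$values,
       U = (1 / rs) * eig$vectors,          # rows scaled: D^(-1/2) V
       Uinv = t(eig$vectors) * rep(rs, each = 20))
}

.jtt_cache <- new.env(parent = emptyenv())
get_jtt <- function() {
  if (is.null(.jtt_cache$model)) .jtt_cache$model <- jtt_model()
  .jtt_cache$model
}

# Transition probability matrix P(t) = exp(Qt) under the JTT model.
jtt_prob <- function(t, model = get_jtt()) {
  P <- model$U %*% (exp(model$values * t) * model$Uinv)
  P[P < 0] <- 0
  P
}

#' Maximum-likelihood JTT distance between two aligned protein sequences
#'
#' Finds the branch length `t` (expected substitutions per site under the
#' rate-normalized JTT model) maximizing the pairwise likelihood
#' `sum_sites log(pi_a P_ab(t))`. Columns where either sequence has a gap or
#' a non-standard residue are dropped (pairwise deletion). The optimum is
#' located by bounded one-dimensional search on `[0, t_max]`; a saturated
#' pair (optimum at the bound) returns `t_max` with a warning.
#'
#' @param aligned_a,aligned_b Aligned protein strings (or character
#'   vectors) of equal length.
#' @param t_max Search bound (default 10 substitutions/site).
#' @param tol Optimizer tolerance.
#' @return Estimated distance in substitutions per site.
#' @export
jtt_distance <- function(aligned_a, aligned_b, t_max = 10, tol = 1e-8) {
  a <- if (length(aligned_a) > 1) aligned_a else strsplit(toupper(aligned_a), "")[[1]]
  b <- if (length(aligned_b) > 1) aligned_b else strsplit(toupper(aligned_b), "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  a <- toupper(a); b <- toupper(b)
  ok <- a %in% AA20 & b %in% AA20
  if (!any(ok)) stop("no comparable columns (all gap/ambiguous)")
  ia <- match(a[ok], AA20); ib <- match(b[ok], AA20)
  # site-pattern compression: one weight per residue pair
  pat <- ia + 20L * (ib - 1L)
  cnt <- tabulate(pat, nbins = 400L)
  nz <- which(cnt > 0)
  wi <- (nz - 1L) %% 20L + 1L
  wj <- (nz - 1L) %/% 20L + 1L
  w <- cnt[nz]
  model <- get_jtt()
  if (all(wi == wj)) return(0)
  nll <- function(t) {
    P <- jtt_prob(t, model)
    lk <- model$pi[wi] * P[cbind(wi, wj)]
    if (any(lk <= 0)) return(Inf)
    -sum(w * log(lk))
  }
  opt <- stats::optimize(nll, c(0, t_max), tol = tol)
  t_hat <- opt$minimum
  if (t_hat > t_max - 1e-4 && nll(t_max) <= opt$objective + 1e-9) {
    warning("distance saturated at t_max")
    return(t_max)
  }
  # optimize() never evaluates the interval ends; snap near-zero to zero
  if (t_hat < 1e-6 && nll(0) <= opt$objective) return(0)
  t_hat
}

#' Pairwise JTT distance matrix for an alignment
#'
#' @param aln Character matrix (taxa x sites, rownames = taxon labels).
#' @param ... Passed to [jtt_distance()].
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
jtt_distance_matrix <- function(aln, ...) {
  n <- nrow(aln)
  taxa <- rownames(aln)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- jtt_distance(aln[i, ], aln[j, ], ...)
    }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj]); consistent on additive
#' matrices, where it reproduces the generating tree's path metric exactly.
#' Negative branch-length estimates are clamped to zero with the excess
#' transferred to the sibling edge at the same node, preserving tip-to-tip
#' path lengths (standard practice for NJ output).
#'
#' @param dm Symmetric distance matrix (or `dist`), >= 3 taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining needs >= 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  tree <- ape::nj(stats::as.dist(dm))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    excess <- tree$edge.length[e]
    parent <- tree$edge[e, 1]
    sib <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sib)) {
      s <- sib[1]
      tree$edge.length[s] <- tree$edge.length[s] + excess
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree with bootstrap support from protein families
#'
#' Concatenates the aligned families into a supermatrix, estimates the tree
#' (JTT ML distances + NJ), then resamples supermatrix columns with
#' replacement `n_reps` times, recomputing distances and tree each time.
#' Support of an internal edge is the percentage of replicates containing
#' the same bipartition, attached as integer node labels.
#'
#' @param families List of aligned character matrices (same taxa), e.g.
#'   from [evolve_protein_families()], or a single matrix.
#' @param n_reps Bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @param ... Passed to [jtt_distance()].
#' @return An [ape::phylo] tree; `$node.label` holds support percentages
#'   (root label empty).
#' @export
bootstrap_support <- function(families, n_reps = 500L, seed = 1L, ...) {
  if (is.matrix(families)) families <- list(families)
  taxa <- rownames(families[[1]])
  for (f in families)
    if (!identical(rownames(f), taxa))
      stop("all families must share the same taxa in the same order")
  sm <- do.call(cbind, families)
  tree <- neighbor_joining(jtt_distance_matrix(sm, ...))
  counts <- with_seed(sub_seed(seed, "bootstrap"), {
    ape::boot.phylo(tree, sm,
                    function(x) neighbor_joining(jtt_distance_matrix(x, ...)),
                    B = n_reps, quiet = TRUE, trees = FALSE)
  })
  supp <- as.integer(round(100 * counts / n_reps))
  tree$node.label <- c("", supp[-1])
  tree
}

#' Write a tree with support labels to Newick
#'
#' @param tree [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
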