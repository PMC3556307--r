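test_that("local alignment reproduces the closed-form bit score", {
  s <- rand_dna(100, seed = 61)
  res <- local_align(s, s)
  expect_equal(res$raw_score, 200)
  expect_equal(res$bit_score, (0.625 * 200 - log(0.41)) / log(2))
  expect_equal(res$alignment_length, 100)
  expect_equal(res$score_density, res$bit_score / 100)
  expect_equal(res$e_value, 100 * 100 * 2^(-res$bit_score))
  expect_error(local_align(s, s, align_scoring(lambda = 0)), "lambda")
})

test_that("unrelated random sequences stay below the edge threshold", {
  set.seed(62)
  ev <- replicate(20, {
    local_align(rand_dna(150), rand_dna(150))$e_value
  })
  expect_true(all(ev > 1e-5))
})

test_that("graph building connects identical pairs on either strand", {
  s <- rand_dna(120, seed = 63)
  g <- build_graph(c(u1 = s, u2 = s))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$strand, "+")
  expect_equal(g$edges$score_density, g$edges$bit_score / 120)

  g2 <- build_graph(c(u1 = s, u2 = revcomp_chr(s)))
  expect_equal(nrow(g2$edges), 1)
  expect_equal(g2$edges$strand, "-")

  g3 <- build_graph(c(only = s))
  expect_equal(length(g3$nodes), 1)
  expect_equal(nrow(g3$edges), 0)
  cl <- mcl(g3)
  expect_equal(cl$cluster, 1)
})

test_that("MCL keeps disconnected components separate and partitions nodes", {
  # two triangles
  A <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  cl <- mcl(A)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[1:3])), 1)
  expect_equal(length(unique(cl$cluster[4:6])), 1)

  # fuzz: random multi-component graphs; partition + component separation
  set.seed(64)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    sizes <- sample(2:6, k, replace = TRUE)
    n <- sum(sizes)
    A <- matrix(0, n, n)
    off <- cumsum(c(0, sizes))
    memb <- rep(seq_len(k), sizes)
    for (c in seq_len(k)) {
      idx <- (off[c] + 1):off[c + 1]
      for (i in idx) for (j in idx) if (i < j && runif(1) < 0.8)
        A[i, j] <- A[j, i] <- runif(1, 0.5, 1)
      # ensure connectivity within the block (path)
      for (i in idx[-1]) A[i - 1, i] <- A[i, i - 1] <-
          max(A[i - 1, i], 0.6)
    }
    cl <- mcl(A)
    expect_equal(length(cl$cluster), n)            # every node assigned once
    # nodes in different generated components never share a cluster
    for (c1 in seq_len(k - 1)) for (c2 in (c1 + 1):k) {
      expect_equal(length(intersect(cl$cluster[memb == c1],
                                    cl$cluster[memb == c2])), 0)
    }
  }
})

test_that("MCL splits two cliques joined by a weak bridge", {
  n <- 10
  A <- matrix(0, n, n)
  for (i in 1:5) for (j in 1:5) if (i != j) A[i, j] <- 1
  for (i in 6:10) for (j in 6:10) if (i != j) A[i, j] <- 1
  A[5, 6] <- A[6, 5] <- 0.01
  cl <- mcl(A, inflation = 2.0)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[1:5])), 1)
  expect_equal(length(unique(cl$cluster[6:10])), 1)

  # permuting node order permutes but does not change the partition
  p <- sample(n)
  clp <- mcl(A[p, p, drop = FALSE])
  expect_equal(length(unique(clp$cluster)), 2)
  back <- clp$cluster[order(p)]
  expect_equal(length(unique(back[1:5])), 1)
  expect_equal(length(unique(back[6:10])), 1)
})

test_that("k-mer profiles skip invalid windows and normalize to 1", {
  p <- kmer_profile("AAAAA", 5)
  expect_equal(unname(p[1, "AAAAA"]), 1)
  expect_equal(sum(p), 1)

  p2 <- kmer_profile("AANGGGGG", 5)   # windows through N skipped
  expect_equal(sum(p2), 1)
  expect_equal(unname(p2[1, "GGGGG"]), 1)   # only the GGGGG window is valid

  expect_warning(p3 <- kmer_profile("AANAA", 5), "no valid")
  expect_equal(sum(p3), 0)

  set.seed(65)
  p4 <- kmer_profile(vapply(1:5, function(i) rand_dna(60), ""), 5)
  expect_equal(unname(rowSums(p4)), rep(1, 5))
})

test_that("MCE kernel equals geodesic distances on the MST", {
  # 3 points on a line: MST path with edges 1 and 2
  prof <- matrix(c(0, 1, 3), ncol = 1)
  emb <- mce_embed(prof, d = 2)
  expect_equal(sort(unique(as.vector(emb$kernel))), c(0, 1, 2, 3))
  expect_equal(emb$kernel[1, 3], 3)

  # random instances: kernel == igraph shortest paths over MST edges;
  # MST weight == igraph MST weight (independent implementations)
  set.seed(66)
  for (rep in 1:6) {
    n <- sample(8:50, 1)
    prof <- matrix(runif(n * 6), n)
    emb <- mce_embed(prof, d = 3)
    D <- as.matrix(stats::dist(prof))
    ig <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                              weighted = TRUE)
    im <- igraph::mst(ig)
    expect_equal(sum(emb$mst$w), sum(igraph::E(im)$weight))
    gd <- igraph::distances(im)
    expect_equal(unname(emb$kernel), unname(gd), tolerance = 1e-12)
    expect_true(all(diff(emb$singular_values) <= 1e-12))
    expect_equal(t(emb$kernel), emb$kernel)
    expect_true(all(diag(emb$kernel) == 0))
  }
  expect_error(mce_embed(matrix(0, 2, 2), d = 5), "exceed")
})

test_that("planted UCR families are recovered as exactly two clusters", {
  set.seed(67)
  m1 <- rand_dna(250); m2 <- rand_dna(250)
  seqs <- c(make_family(m1, 6, 0.05), make_family(m2, 5, 0.05))
  names(seqs) <- paste0("u", seq_along(seqs))
  cl <- mcl(build_graph(seqs))
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[1:6])), 1)
  expect_equal(length(unique(cl$cluster[7:11])), 1)
  expect_false(cl$cluster[1] == cl$cluster[7])

  # families separate in the top embedding dimensions (positive silhouette).
  # dimension 1 of a non-centered distance kernel is the trivial centrality
  # axis, so separation is assessed in the leading 2-D embedding.
  prof <- kmer_profile(seqs, 5)
  emb <- mce_embed(prof, 2)
  lab <- rep(1:2, c(6, 5))
  sil <- silhouette_2d(emb$coords, lab)
  expect_gt(mean(sil), 0)
})
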