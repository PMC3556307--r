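# Independent brute-force oracles used across the suite. These deliberately
# use different algorithms from the package implementations.

rand_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

mutate_dna <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), k)
  for (q in pos) v[q] <- sample(setdiff(c("A", "C", "G", "T"), v[q]), 1)
  paste(v, collapse = "")
}

revcomp_chr <- function(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")

# All maximal exact matches >= min_len between two sequences, one strand,
# by explicit diagonal scanning: a MEM is a maximal run of agreeing ACGT
# positions along a diagonal (offset j - i constant).
oracle_mems_one_strand <- function(a, b, min_len) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  acgt <- c("A", "C", "G", "T")
  out <- list()
  for (off in (-(n - 1)):(m - 1)) {
    i0 <- max(1L, 1L - off); i1 <- min(n, m - off)
    if (i1 - i0 + 1L < min_len) next
    ii <- i0:i1
    eq <- av[ii] == bv[ii + off] & av[ii] %in% acgt & bv[ii + off] %in% acgt
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      sa <- ii[starts[k]] - 1L             # 0-based
      out[[length(out) + 1L]] <- c(sa, sa + off, r$lengths[k])
    }
  }
  if (!length(out))
    return(data.frame(start_a = integer(), start_b = integer(),
                      length = integer()))
  m <- do.call(rbind, out)
  data.frame(start_a = m[, 1], start_b = m[, 2], length = m[, 3])
}

# Both-strand MEM oracle in find_mems() output coordinates.
oracle_mems <- function(a, b, min_len) {
  fw <- oracle_mems_one_strand(a, b, min_len)
  fw$strand <- rep("+", nrow(fw))
  rc <- oracle_mems_one_strand(a, revcomp_chr(b), min_len)
  if (nrow(rc)) {
    rc$start_b <- nchar(b) - rc$start_b - rc$length
    rc$strand <- "-"
  } else rc$strand <- character(0)
  out <- rbind(fw, rc)
  out[order(out$start_a, out$start_b, out$strand), , drop = FALSE]
}

# Canonical key set for comparing match tables (single-scaffold tests).
match_key <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(sprintf("%d:%d:%d:%s", df$start_a, df$start_b, df$length, df$strand))
}

# Brute-force exact tandem scan over all (start, period) pairs.
oracle_tandem <- function(s, max_period, min_copies, min_span) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  acgt <- c("A", "C", "G", "T")
  seen <- character(0)
  res <- list()
  for (p in seq_len(min(max_period, n - 1L))) {
    for (st in seq_len(n - p)) {
      # extend maximal run of v[j] == v[j+p] starting at st
      if (st > 1 && v[st - 1] == v[st - 1 + p] &&
          v[st - 1] %in% acgt && v[st - 1 + p] %in% acgt) next  # not maximal
      j <- st; run <- 0L
      while (j + p <= n && v[j] == v[j + p] && v[j] %in% acgt &&
             v[j + p] %in% acgt) { run <- run + 1L; j <- j + 1L }
      if (run == 0L) next
      span <- run + p
      if (span >= min_span && span / p >= min_copies) {
        key <- paste(st - 1L, st - 1L + span)
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          res[[length(res) + 1L]] <- c(st - 1L, st - 1L + span)
        }
      }
    }
  }
  if (!length(res)) return(data.frame(start = integer(), end = integer()))
  m <- unique(do.call(rbind, res))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}

# Exhaustive upper-tail hypergeometric by direct combinatorial summation.
oracle_hyper <- function(G, g, D, d) {
  i <- d:min(D, g)
  sum(choose(D, i) * choose(G - D, g - i)) / choose(G, g)
}

# Exhaustive upper-tail binomial by enumerating all 2^n outcomes.
oracle_binom_enum <- function(x, n, p) {
  total <- 0
  for (mask in 0:(2^n - 1)) {
    k <- sum(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (k >= x) total <- total + p^k * (1 - p)^(n - k)
  }
  total
}

# Mean silhouette over Euclidean distances in an embedding (2 groups).
silhouette_2d <- function(coords, lab) {
  D <- as.matrix(stats::dist(coords))
  vapply(seq_len(nrow(D)), function(i) {
    a <- mean(D[i, setdiff(which(lab == lab[i]), i)])
    b <- mean(D[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, 1)
}

# Random connected cluster of sequences: copies of one master with <= 5%
# divergence (used for planted-family clustering tests).
make_family <- function(master, n, div = 0.05) {
  vapply(seq_len(n), function(i)
    mutate_dna(master, max(1L, round(div * nchar(master)))), character(1))
}
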