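#' Representative consensus sequence of a cluster
#'
#' Center-star consensus: the member with the highest summed pairwise local
#' alignment score is the center; every other member is globally aligned to
#' it; per center column the majority symbol wins (gap-majority columns are
#' dropped; base ties break alphabetically). Insertions relative to the
#' center are not voted on — for the low-divergence clusters this consensus
#' serves, such columns would be gap-majority and dropped anyway.
#'
#' @param member_sequences Character vector or `DNAStringSet` (>= 1).
#' @param scoring An [align_scoring] object (center selection).
#' @return Consensus DNA string.
#' @export
consensus_sequence <- function(member_sequences,
                               scoring = align_scoring()) {
  if (methods::is(member_sequences, "DNAStringSet"))
    member_sequences <- as.character(member_sequences)
  n <- length(member_sequences)
  if (n == 0) stop("empty cluster: no member sequences")
  if (n == 1) return(unname(toupper(member_sequences[[1]])))
  sq <- toupper(member_sequences)
  tot <- numeric(n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- local_align(sq[i], sq[j], scoring)$raw_score
    tot[i] <- tot[i] + s; tot[j] <- tot[j] + s
  }
  center <- which.max(tot)
  cen <- sq[center]
  L <- nchar(cen)
  # votes[row, col]: symbol of member `row` at center column `col`
  votes <- matrix("-", n, L)
  votes[center, ] <- strsplit(cen, "")[[1]]
  for (i in seq_len(n)[-center]) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::BString(sq[i]), Biostrings::BString(cen), type = "global",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    col <- cumsum(as_ != "-")          # center column index per aln column
    keep <- as_ != "-"
    votes[i, col[keep]] <- ap[keep]
  }
  cons <- character(0)
  symbols <- c("A", "C", "G", "T")
  for (c in seq_len(L)) {
    v <- votes[, c]
    ng <- sum(v == "-")
    cnt <- vapply(symbols, function(s) sum(v == s), 1L)
    if (ng > max(cnt)) next              # gap-majority column dropped
    cons <- c(cons, symbols[which.max(cnt)])  # alphabetical tie-break
  }
  paste(cons, collapse = "")
}

#' Build a species-proportional random background sequence
#'
#' Concatenates segments sampled uniformly (seeded) from the unmasked
#' regions of each species' genome. Each species contributes a share of the
#' total equal to its fraction in the cluster composition, rounded by the
#' largest-remainder method so the output length is exactly `total_length`.
#'
#' @param fractions Named numeric vector of species fractions (sums to 1).
#' @param genomes Named list of [genome] objects covering those species.
#' @param total_length Background length in bp (default 10 kb).
#' @param segment_length Segment mosaic size in bp (default 100).
#' @param seed Integer seed.
#' @return Character DNA string of length `total_length`.
#' @export
build_background <- function(fractions, genomes, total_length = 10000L,
                             segment_length = 100L, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-6) stop("fractions must sum to 1")
  if (total_length < segment_length)
    stop("total_length must be >= segment_length")
  if (!all(names(fractions) %in% names(genomes)))
    stop("genome missing for some species in the composition")
  quota <- floor(fractions * total_length)
  rem <- fractions * total_length - quota
  short <- total_length - sum(quota)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    quota[give] <- quota[give] + 1L
  }
  pieces <- character(0)
  with_seed(sub_seed(seed, "background"), {
    for (sp in names(fractions)) {
      need <- quota[[sp]]
      if (need == 0) next
      g <- genomes[[sp]]
      lens <- scaffold_lengths(g)
      if (max(lens) < segment_length)
        stop(sprintf("genome '%s' shorter than segment_length", sp))
      got <- character(0); got_len <- 0L
      while (got_len < need) {
        take <- min(segment_length, need - got_len)
        seg <- NULL
        for (try in 1:200) {
          sc <- sample(names(lens), 1, prob = lens)
          if (lens[[sc]] < take) next
          s0 <- sample.int(lens[[sc]] - take + 1L, 1) - 1L
          cand <- substr(scaffold_chars(g, sc), s0 + 1L, s0 + take)
          if (!grepl("[^ACGT]", cand)) { seg <- cand; break }
        }
        if (is.null(seg))
          stop(sprintf("could not sample unmasked segment from '%s'", sp))
        got <- c(got, seg); got_len <- got_len + take
      }
      pieces <- c(pieces, got)
    }
  })
  paste(pieces, collapse = "")
}

#' Upper cumulative binomial probability
#'
#' Probability of observing `x` or more successes in `n` trials at success
#' probability `p`: `F(x | n, p) = 1 - sum_{i=0}^{x-1} C(n,i) p^i
#' (1-p)^(n-i)`. Computed via [stats::pbinom] (log-space stable).
#' `F(0) = 1` by the empty-sum convention.
#'
#' @param x Observed count (`0 <= x <= n`).
#' @param n Number of trials.
#' @param p Success probability in `[0, 1]`.
#' @return Upper-tail probability.
#' @export
binomial_upper <- function(x, n, p) {
  if (any(x < 0) || any(x > n) || any(p < 0) || any(p > 1))
    stop("require 0 <= x <= n and 0 <= p <= 1")
  stats::pbinom(x - 1, n, p, lower.tail = FALSE)
}

#' Overrepresented k-mers in a cluster representative
#'
#' For every k-mer occurring on the forward strand of the representative:
#' `x` is its occurrence count (overlaps allowed — the trial model
#' `n = L - k + 1` is the number of sliding windows), and the background
#' probability is estimated from the background sequence with add-one
#' smoothing, `p = (c + 1) / (N - k + 2)`, so background-absent k-mers keep
#' a finite p-value (a 10 kb background undersamples the 65,536 possible
#' 8-mers). The p-value is the upper cumulative binomial `F(x | n, p)`.
#'
#' @param representative Consensus DNA string (length >= k).
#' @param background Background DNA string (length >= k), e.g. from
#'   [build_background()].
#' @param k Word size (default 8).
#' @param report_threshold Rows with `p_value <` this are flagged
#'   (default `1e-4`).
#' @return data.frame (`oligomer`,`x`,`n`,`p`,`p_value`,`flagged`) sorted by
#'   p-value; k-mers absent from the representative are omitted.
#' @export
oligomer_enrichment <- function(representative, background, k = 8L,
                                report_threshold = 1e-4) {
  L <- nchar(representative)
  if (L < k) stop("representative shorter than k")
  Nbg <- nchar(background)
  if (Nbg < k) stop("background shorter than k")
  xs <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(toupper(representative)), width = k)
  cb <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(toupper(background)), width = k)
  present <- which(xs > 0)
  n <- L - k + 1L
  p <- (cb[present] + 1) / (Nbg - k + 2)
  pv <- binomial_upper(as.integer(xs[present]), n, p)
  out <- data.frame(oligomer = names(xs)[present],
                    x = as.integer(xs[present]), n = n, p = as.numeric(p),
                    p_value = as.numeric(pv),
                    flagged = as.numeric(pv) < report_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$oligomer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif overrepresentation for every cluster
#'
#' Builds the center-star representative and the species-proportional 10 kb
#' background per cluster, then scores k-mer overrepresentation.
#'
#' @param clusters Cluster table from [mcl()].
#' @param ucrs UCR table (member sequences and species composition).
#' @param genomes Named list of [genome] objects (background source).
#' @param k Word size (default 8).
#' @param total_length Background length (default 10 kb).
#' @param segment_length Background mosaic segment (default 100 bp).
#' @param report_threshold Flag threshold (default `1e-4`).
#' @param seed Integer seed.
#' @param min_members Skip clusters with fewer members (default 1).
#' @return data.frame of [oligomer_enrichment()] rows with a `cluster`
#'   column prepended.
#' @export
cluster_motifs <- function(clusters, ucrs, genomes, k = 8L,
                           total_length = 10000L, segment_length = 100L,
                           report_threshold = 1e-4, seed = 1L,
                           min_members = 1L) {
  rows <- list()
  for (cl in sort(unique(clusters$cluster))) {
    members <- ucrs[ucrs$ucr_id %in% clusters$id[clusters$cluster == cl], ,
                    drop = FALSE]
    if (nrow(members) < min_members) next
    rep_seq <- consensus_sequence(members$sequence_with_flanks)
    if (nchar(rep_seq) < k) next
    comp <- table(members$species)
    fr <- as.numeric(comp) / sum(comp)
    names(fr) <- names(comp)
    bg <- build_background(fr, genomes, total_length, segment_length,
                           seed = sub_seed(seed, paste0("bg:", cl)))
    tab <- oligomer_enrichment(rep_seq, bg, k, report_threshold)
    if (nrow(tab))
      rows[[length(rows) + 1L]] <- cbind(cluster = cl, tab)
  }
  if (!length(rows))
    return(data.frame(cluster = integer(), oligomer = character(),
                      x = integer(), n = integer(), p = double(),
                      p_value = double(), flagged = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
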