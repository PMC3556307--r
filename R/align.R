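#' Scoring scheme for local alignment
#'
#' Defaults mimic classic blastn: match +2, mismatch -3, gap open 5, gap
#' extend 2 (a gap of length `L` costs `open + L * extend`), with
#' Karlin-Altschul parameters `lambda = 0.625`, `K = 0.41` for converting
#' raw scores to bit scores.
#'
#' @param match,mismatch Substitution scores (match > 0, mismatch < 0).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @param lambda,K Karlin-Altschul parameters (`lambda > 0`, `K > 0`).
#' @return An `align_scoring` object.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                          gap_extend = 2, lambda = 0.625, K = 0.41) {
  if (lambda <= 0) stop("lambda must be positive")
  if (K <= 0) stop("K must be positive")
  mat <- matrix(mismatch, 5, 5,
                dimnames = list(c("A", "C", "G", "T", "N"),
                                c("A", "C", "G", "T", "N")))
  diag(mat)[1:4] <- match
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 matrix = mat),
            class = "align_scoring")
}

#' Optimal local alignment with BLAST-style statistics
#'
#' Smith-Waterman local alignment (via [Biostrings::pairwiseAlignment])
#' under the given scoring scheme. The bit score is
#' `(lambda * raw - ln K) / ln 2` and the E-value is `m * n * 2^-bit` for
#' sequence lengths `m`, `n`. The score density — bit score divided by the
#' number of alignment columns — is the similarity measure used for
#' clustering.
#'
#' @param seq_a,seq_b DNA strings (character or `DNAString`). `N` scores as
#'   a mismatch against everything, including `N`.
#' @param scoring An [align_scoring] object.
#' @return List with `raw_score`, `bit_score`, `alignment_length`,
#'   `score_density`, `e_value`.
#' @export
local_align <- function(seq_a, seq_b, scoring = align_scoring()) {
  stopifnot(inherits(scoring, "align_scoring"))
  a <- toupper(as.character(seq_a)); b <- toupper(as.character(seq_b))
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b), type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  raw <- Biostrings::score(pa)
  alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
  if (alen < 1) alen <- 1L
  bit <- (scoring$lambda * raw - log(scoring$K)) / log(2)
  list(raw_score = raw, bit_score = bit, alignment_length = alen,
       score_density = bit / alen,
       e_value = as.double(nchar(a)) * nchar(b) * 2^(-bit))
}

#' Build a UCR similarity graph
#'
#' Aligns every pair of sequences locally on both relative strands
#' (forward-forward and forward-reverse-complement; best kept, so partially
#' reverse-complementary elements still connect) and keeps an edge when the
#' E-value is at most `max_e`. Edge weight is the score density (bit score
#' per alignment column).
#'
#' @param seqs Named `DNAStringSet` (or character vector) of UCR sequences
#'   with flanks.
#' @param scoring An [align_scoring] object.
#' @param max_e E-value gate for edge existence (default `1e-5`).
#' @return List with `nodes` (character ids) and `edges` (data.frame
#'   `from`,`to`,`bit_score`,`alignment_length`,`score_density`,`e_value`,
#'   `strand`).
#' @export
build_graph <- function(seqs, scoring = align_scoring(), max_e = 1e-5) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) < 1) stop("need at least one sequence")
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  sq <- toupper(as.character(seqs))
  lens <- nchar(sq)
  edges <- list()
  n <- length(sq)
  if (n > 1) {
    bs <- Biostrings::BStringSet(sq)
    bs_rc <- Biostrings::BStringSet(vapply(sq, revcomp, character(1),
                                           USE.NAMES = FALSE))
    for (j in 2:n) {
      idx <- 1:(j - 1)
      # all earlier sequences against subject j, both relative strands
      paf <- Biostrings::pairwiseAlignment(
        bs[idx], bs[[j]], type = "local",
        substitutionMatrix = scoring$matrix,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
      par <- Biostrings::pairwiseAlignment(
        bs[idx], bs_rc[[j]], type = "local",
        substitutionMatrix = scoring$matrix,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
      sf <- Biostrings::score(paf); sr <- Biostrings::score(par)
      use_f <- sf >= sr
      raw <- ifelse(use_f, sf, sr)
      alen <- pmax(ifelse(use_f, Biostrings::nchar(paf),
                          Biostrings::nchar(par)), 1L)
      bit <- (scoring$lambda * raw - log(scoring$K)) / log(2)
      ev <- as.double(lens[idx]) * lens[j] * 2^(-bit)
      keep <- which(ev <= max_e)
      if (length(keep))
        edges[[length(edges) + 1L]] <- data.frame(
          from = ids[idx][keep], to = ids[j], bit_score = bit[keep],
          alignment_length = alen[keep],
          score_density = bit[keep] / alen[keep], e_value = ev[keep],
          strand = ifelse(use_f[keep], "+", "-"), stringsAsFactors = FALSE)
    }
  }
  list(nodes = ids,
       edges = if (length(edges)) do.call(rbind, edges)
       else data.frame(from = character(), to = character(),
                       bit_score = double(), alignment_length = integer(),
                       score_density = double(), e_value = double(),
                       strand = character(), stringsAsFactors = FALSE))
}
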