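#' Find all maximal exact matches between two genomes
#'
#' Reports every maximal exact match (MEM) of at least `min_length` bp
#' between two hard-masked genomes, on both strands, including non-unique
#' occurrences. A MEM cannot be extended by one base to the left or right in
#' both genomes simultaneously; `N` (masked or assembly gap) never matches
#' anything, so matches stop at masked bases. Scaffold boundaries are hard
#' separators. Minus-strand matches are reported with `strand = "-"` and
#' `start_b` on the forward strand of genome `b` (the forward-strand
#' interval whose reverse complement equals the `a` substring).
#'
#' Self-comparison (`a` and `b` the same species) reports plus-strand
#' self-identity and palindromic matches trivially and is rejected.
#'
#' @param genome_a,genome_b [genome] objects for two different species.
#' @param min_length Minimum match length in bp (the ultraconserved-element
#'   threshold; 50 for the standard set, 30 for the short set).
#' @return data.frame with columns `species_a`, `scaffold_a`, `start_a`,
#'   `end_a`, `species_b`, `scaffold_b`, `start_b`, `end_b`, `strand`,
#'   `length` (coordinates 0-based half-open, forward strand).
#' @export
find_mems <- function(genome_a, genome_b, min_length = 50L) {
  stopifnot(inherits(genome_a, "genome"), inherits(genome_b, "genome"))
  if (identical(genome_a$species, genome_b$species))
    stop("self-comparison is not supported; species labels are identical")
  if (min_length < 1) stop("min_length must be >= 1")
  res <- list()
  for (sca in names(genome_a$seqs)) {
    sa <- toupper(scaffold_chars(genome_a, sca))
    for (scb in names(genome_b$seqs)) {
      sb <- toupper(scaffold_chars(genome_b, scb))
      lb <- nchar(sb)
      fw <- .find_mems_cpp(sa, sb, as.integer(min_length))
      if (nrow(fw))
        res[[length(res) + 1L]] <- data.frame(
          species_a = genome_a$species, scaffold_a = sca,
          start_a = fw[, 1], end_a = fw[, 1] + fw[, 3],
          species_b = genome_b$species, scaffold_b = scb,
          start_b = fw[, 2], end_b = fw[, 2] + fw[, 3],
          strand = "+", length = fw[, 3], stringsAsFactors = FALSE)
      rc <- .find_mems_cpp(sa, revcomp(sb), as.integer(min_length))
      if (nrow(rc)) {
        sb0 <- lb - rc[, 2] - rc[, 3]
        res[[length(res) + 1L]] <- data.frame(
          species_a = genome_a$species, scaffold_a = sca,
          start_a = rc[, 1], end_a = rc[, 1] + rc[, 3],
          species_b = genome_b$species, scaffold_b = scb,
          start_b = sb0, end_b = sb0 + rc[, 3],
          strand = "-", length = rc[, 3], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty_matches())
  out <- do.call(rbind, res)
  out <- out[order(out$scaffold_a, out$start_a, out$scaffold_b, out$start_b,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_matches <- function() {
  data.frame(species_a = character(), scaffold_a = character(),
             start_a = integer(), end_a = integer(),
             species_b = character(), scaffold_b = character(),
             start_b = integer(), end_b = integer(),
             strand = character(), length = integer(),
             stringsAsFactors = FALSE)
}

#' Re-mask discovered matches and trim or discard them
#'
#' Runs the repeat detectors again on each match's sequence (second-round
#' masking): a match is trimmed to its longest unmasked run and dropped when
#' that run is shorter than `min_length`. Coordinates are updated
#' consistently in both species; on a minus-strand match a trim of `o` bases
#' from the left of the `a` interval removes `o` bases from the right of the
#' forward-strand `b` interval.
#'
#' @param matches Match table from [find_mems()].
#' @param genome_a The `a`-side [genome] (source of match sequence).
#' @param min_length Matches trimmed below this length are dropped.
#' @param ... Passed to [find_tandem_repeats()] / [find_low_complexity()]
#'   via [mask_match_sequence()] parameters `max_period`, `min_copies`,
#'   `min_span`, `window`, `entropy_threshold`.
#' @return Filtered and trimmed match table.
#' @export
remask_matches <- function(matches, genome_a, min_length = 50L, ...) {
  if (nrow(matches) == 0) return(matches)
  keep <- logical(nrow(matches))
  for (r in seq_len(nrow(matches))) {
    sq <- substr(scaffold_chars(genome_a, matches$scaffold_a[r]),
                 matches$start_a[r] + 1L, matches$end_a[r])
    iv <- mask_match_sequence(sq, ...)
    run <- longest_unmasked_run(nchar(sq), iv)
    if (is.null(run) || (run[2] - run[1]) < min_length) next
    keep[r] <- TRUE
    o <- run[1]; len <- run[2] - run[1]
    old_len <- matches$length[r]
    matches$start_a[r] <- matches$start_a[r] + o
    matches$end_a[r] <- matches$start_a[r] + len
    if (matches$strand[r] == "+") {
      matches$start_b[r] <- matches$start_b[r] + o
    } else {
      matches$start_b[r] <- matches$start_b[r] + (old_len - o - len)
    }
    matches$end_b[r] <- matches$start_b[r] + len
    matches$length[r] <- len
  }
  out <- matches[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Both detectors on one match sequence; returns pooled mask intervals.
mask_match_sequence <- function(sq, max_period = 6L, min_copies = 4,
                                min_span = 24L, window = 64L,
                                entropy_threshold = 1.5) {
  rbind(find_tandem_repeats(sq, max_period, min_copies, min_span),
        find_low_complexity(sq, window, entropy_threshold))
}

#' Write a match table to TSV
#'
#' @param matches Match table from [find_mems()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
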