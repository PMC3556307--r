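#' Genome container
#'
#' A genome is a set of named scaffold sequences for one species, held as a
#' [Biostrings::DNAStringSet]. Hard-masked positions are represented by the
#' letter `N`; an `N` never matches any base (including another `N`) anywhere
#' in the pipeline.
#'
#' @param seqs A `DNAStringSet` (or named character vector) of scaffold
#'   sequences. Names are scaffold identifiers and must be unique.
#' @param species Single species label.
#' @return An object of class `genome`.
#' @export
genome <- function(seqs, species) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  stopifnot(methods::is(seqs, "DNAStringSet"))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("scaffolds must have unique names")
  if (!is.character(species) || length(species) != 1L || !nzchar(species))
    stop("'species' must be a single non-empty label")
  structure(list(species = species, seqs = seqs), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> species '%s': %d scaffold(s), %s bp total\n",
              x$species, length(x$seqs),
              format(sum(Biostrings::width(x$seqs)), big.mark = ",")))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' @param path FASTA file.
#' @param species Species label; defaults to the file name without extension.
#' @return A [genome].
#' @export
read_genome <- function(path, species = NULL) {
  if (is.null(species))
    species <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  seqs <- Biostrings::readDNAStringSet(path)
  # keep only the first whitespace-delimited token of each FASTA header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome(seqs, species)
}

#' Write a genome to FASTA
#'
#' @param g A [genome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(g, path) {
  stopifnot(inherits(g, "genome"))
  Biostrings::writeXStringSet(g$seqs, path)
  invisible(path)
}

scaffold_lengths <- function(g) {
  stats::setNames(Biostrings::width(g$seqs), names(g$seqs))
}

# Retrieve scaffold sequence as a plain character string.
scaffold_chars <- function(g, scaffold) {
  as.character(g$seqs[[scaffold]])
}

#' Reverse complement of a DNA string
#' @param x Character DNA string.
#' @return Character string.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Derive a named sub-seed from a global seed
#'
#' All generators in the package draw their randomness from one global seed,
#' expanded into per-stage seeds by hashing a stage name. This keeps stages
#' independently reproducible: re-running one stage with the same global seed
#' gives the same stream regardless of what ran before it.
#'
#' @param seed Integer global seed.
#' @param name Stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
sub_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((h + as.double(seed) %% 2147483647) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 0-based half-open interval data.frame constructor used across modules.
interval_df <- function(scaffold = character(), start = integer(),
                        end = integer(), kind = character()) {
  data.frame(scaffold = as.character(scaffold), start = as.integer(start),
             end = as.integer(end), kind = as.character(kind),
             stringsAsFactors = FALSE)
}
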