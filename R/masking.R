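#' Find exact tandem repeats in a sequence
#'
#' Detects maximal runs of exact tandem repetition: an interval is reported
#' when it is covered by at least `min_copies` consecutive repetitions (the
#' last copy may be partial) of a unit of length at most `max_period`, spans
#' at least `min_span` bp, and cannot be extended in either direction for
#' that period. Detection is exact (substitutions/indels inside the array
#' break it); users needing approximate-repeat sensitivity can supply an
#' external mask ([load_external_mask()]). Intervals satisfying several
#' periods are reported once.
#'
#' Defaults (`max_period` 6, `min_copies` 4, `min_span` 24) catch
#' homopolymers and microsatellites while leaving random sequence untouched.
#'
#' @param sequence DNA string (character or `DNAString`). Non-ACGT letters
#'   never match, so `N` runs break tandem arrays.
#' @param max_period Maximum unit length (>= 1).
#' @param min_copies Minimum number of unit copies (>= 2, may be fractional).
#' @param min_span Minimum total span in bp.
#' @param scaffold Scaffold name recorded in the output.
#' @return data.frame of 0-based half-open intervals
#'   (`scaffold`,`start`,`end`,`kind = "tandem"`).
#' @export
find_tandem_repeats <- function(sequence, max_period = 6L, min_copies = 4,
                                min_span = 24L, scaffold = "seq") {
  if (max_period < 1) stop("max_period must be >= 1")
  s <- strsplit(toupper(as.character(sequence)), "")[[1]]
  n <- length(s)
  if (n == 0) return(interval_df())
  ok <- s %in% c("A", "C", "G", "T")
  res <- list()
  for (p in seq_len(min(max_period, n - 1L))) {
    eq <- s[1:(n - p)] == s[(p + 1):n] & ok[1:(n - p)] & ok[(p + 1):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run <- r$lengths[j]            # number of matching (i, i+p) pairs
      span <- run + p                # bases covered by the array
      if (span >= min_span && span / p >= min_copies) {
        res[[length(res) + 1L]] <- c(starts[j] - 1L, starts[j] - 1L + span)
      }
    }
  }
  if (!length(res)) return(interval_df())
  m <- unique(do.call(rbind, res))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  interval_df(scaffold, m[, 1], m[, 2], "tandem")
}

#' Find low-complexity sequence by windowed entropy
#'
#' Slides a window along the sequence and masks the union of all windows
#' whose mononucleotide Shannon entropy falls below a threshold. A uniform
#' random 64-mer has entropy close to 2 bits, so the default threshold of
#' 1.5 bits masks homopolymer-rich and strongly skewed sequence only.
#'
#' @param sequence DNA string. Non-ACGT letters are ignored inside a window
#'   (entropy is computed over the ACGT counts present).
#' @param window Window width in bp (>= 4). Sequences shorter than the
#'   window yield no intervals.
#' @param entropy_threshold Threshold in bits; windows with entropy strictly
#'   below it are masked.
#' @param scaffold Scaffold name recorded in the output.
#' @return data.frame of 0-based half-open intervals (`kind =
#'   "low_complexity"`), merged into maximal runs.
#' @export
find_low_complexity <- function(sequence, window = 64L, entropy_threshold = 1.5,
                                scaffold = "seq") {
  if (window < 4) stop("window must be >= 4")
  sq <- Biostrings::DNAString(toupper(as.character(sequence)))
  if (length(sq) < window) return(interval_df())
  cnt <- Biostrings::letterFrequencyInSlidingView(sq, window,
                                                  c("A", "C", "G", "T"))
  tot <- rowSums(cnt)
  pf <- cnt / pmax(tot, 1L)
  lp <- ifelse(pf > 0, log2(pf), 0)
  ent <- -rowSums(pf * lp)
  hit <- which(tot > 0 & ent < entropy_threshold)
  if (!length(hit)) return(interval_df())
  iv <- IRanges::reduce(IRanges::IRanges(start = hit, width = window))
  interval_df(scaffold, BiocGenerics::start(iv) - 1L, BiocGenerics::end(iv),
              "low_complexity")
}

#' Hard-mask intervals in a genome
#'
#' Replaces every base inside the given intervals with `N`. Hard masking
#' (rather than lowercase soft masking) guarantees the discovery stage can
#' never match through a repeat: `N` matches nothing, including another `N`.
#' Idempotent.
#'
#' @param g A [genome].
#' @param intervals data.frame (`scaffold`,`start`,`end`), 0-based half-open.
#' @return The masked [genome].
#' @export
apply_mask <- function(g, intervals) {
  stopifnot(inherits(g, "genome"))
  if (is.null(intervals) || nrow(intervals) == 0) return(g)
  lens <- scaffold_lengths(g)
  bad <- !(intervals$scaffold %in% names(lens)) |
    intervals$start < 0 | intervals$end > lens[intervals$scaffold] |
    intervals$end <= intervals$start
  if (any(bad)) {
    j <- which(bad)[1]
    stop(sprintf("interval out of bounds or invalid: %s:[%d,%d)",
                 intervals$scaffold[j], intervals$start[j], intervals$end[j]))
  }
  seqs <- g$seqs
  for (sc in unique(intervals$scaffold)) {
    iv <- intervals[intervals$scaffold == sc, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
    repl <- vapply(BiocGenerics::width(ir),
                   function(w) paste(rep("N", w), collapse = ""), character(1))
    seqs[[sc]] <- Biostrings::replaceAt(seqs[[sc]], ir, repl)
  }
  genome(seqs, g$species)
}

#' Mask a whole genome (tandem + low-complexity + external)
#'
#' Runs both detectors on every scaffold, pools the intervals with any
#' external mask, and hard-masks the genome.
#'
#' @param g A [genome].
#' @param max_period,min_copies,min_span Tandem detector settings.
#' @param window,entropy_threshold Entropy detector settings.
#' @param external Optional data.frame of external mask intervals
#'   (e.g. from [load_external_mask()]).
#' @return List with `genome` (masked) and `intervals` (all mask intervals).
#' @export
mask_genome <- function(g, max_period = 6L, min_copies = 4, min_span = 24L,
                        window = 64L, entropy_threshold = 1.5,
                        external = NULL) {
  ivs <- list()
  for (sc in names(g$seqs)) {
    s <- scaffold_chars(g, sc)
    ivs[[length(ivs) + 1L]] <- find_tandem_repeats(
      s, max_period, min_copies, min_span, scaffold = sc)
    ivs[[length(ivs) + 1L]] <- find_low_complexity(
      s, window, entropy_threshold, scaffold = sc)
  }
  if (!is.null(external)) ivs[[length(ivs) + 1L]] <- external
  iv <- do.call(rbind, ivs)
  list(genome = apply_mask(g, iv), intervals = iv)
}

#' Load an external mask from a BED file
#'
#' BED intervals are 0-based half-open per the BED standard. Use this to
#' supply masks from external repeat annotation tools alongside the built-in
#' detectors.
#'
#' @param path BED file (>= 3 columns).
#' @return data.frame of intervals with `kind = "external"`.
#' @export
load_external_mask <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(interval_df())
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
    st <- suppressWarnings(as.integer(f[2])); en <- suppressWarnings(as.integer(f[3]))
    if (is.na(st) || is.na(en))
      stop(sprintf("malformed BED line %d: non-numeric coordinates", i))
    if (en <= st) stop(sprintf("malformed BED line %d: end <= start", i))
    out[[i]] <- data.frame(scaffold = f[1], start = st, end = en,
                           kind = "external", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write mask intervals to BED
#'
#' @param intervals Interval data.frame (0-based half-open).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- intervals[, c("scaffold", "start", "end")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Longest unmasked run of a sequence given mask intervals on [0, n).
# Returns c(start, end) half-open, or NULL when fully masked.
longest_unmasked_run <- function(n, intervals) {
  masked <- rep(FALSE, n)
  if (!is.null(intervals) && nrow(intervals))
    for (j in seq_len(nrow(intervals))) {
      s <- max(intervals$start[j], 0L); e <- min(intervals$end[j], n)
      if (e > s) masked[(s + 1):e] <- TRUE
    }
  r <- rle(!masked)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  best <- keep[which.max(r$lengths[keep])]
  c(starts[best] - 1L, ends[best])
}
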