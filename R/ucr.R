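#' Project pairwise matches onto one species
#'
#' Every match involving the species contributes its interval in that
#' species, labeled with the partner species. Minus-strand matches already
#' carry forward-strand coordinates, so projection is pure bookkeeping.
#'
#' @param match_list List of match tables from [find_mems()] (any subset of
#'   species pairs).
#' @param species Species label to project onto.
#' @return data.frame (`scaffold`,`start`,`end`,`partner`,`match_id`),
#'   0-based half-open.
#' @export
project_matches <- function(match_list, species) {
  if (inherits(match_list, "data.frame")) match_list <- list(match_list)
  res <- list()
  for (k in seq_along(match_list)) {
    m <- match_list[[k]]
    if (!nrow(m)) next
    ida <- m$species_a == species
    if (any(ida))
      res[[length(res) + 1L]] <- data.frame(
        scaffold = m$scaffold_a[ida], start = m$start_a[ida],
        end = m$end_a[ida], partner = m$species_b[ida],
        match_id = sprintf("m%d.%d", k, which(ida)), stringsAsFactors = FALSE)
    idb <- m$species_b == species
    if (any(idb))
      res[[length(res) + 1L]] <- data.frame(
        scaffold = m$scaffold_b[idb], start = m$start_b[idb],
        end = m$end_b[idb], partner = m$species_a[idb],
        match_id = sprintf("m%d.%d", k, which(idb)), stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), partner = character(),
                      match_id = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Merge projected elements into ultraconserved regions (UCRs)
#'
#' Joins overlapping elements (sharing at least one base; book-ended
#' intervals stay separate) repeatedly until no two overlap — the connected
#' components of the overlap relation — and attaches up to `flank` bp of
#' genomic sequence on each side, truncated at scaffold ends. The
#' `conserved_with` set of a UCR is the union of partner species over its
#' source elements.
#'
#' @param intervals Labeled interval table from [project_matches()].
#' @param g The species' [genome] (flank sequence source).
#' @param flank Flank width in bp (default 50).
#' @return data.frame with one row per UCR: `ucr_id`, `species`, `scaffold`,
#'   `start`, `end` (0-based half-open), `conserved_with` (comma-joined),
#'   `n_elements`, `flank_left`, `flank_right`, `sequence_with_flanks`.
#' @export
merge_to_ucrs <- function(intervals, g, flank = 50L) {
  stopifnot(inherits(g, "genome"))
  if (!nrow(intervals)) return(empty_ucrs(g$species))
  lens <- scaffold_lengths(g)
  if (any(intervals$start < 0) ||
      any(intervals$end > lens[intervals$scaffold]))
    stop("interval outside genome bounds")
  res <- list()
  for (sc in unique(intervals$scaffold)) {
    iv <- intervals[intervals$scaffold == sc, , drop = FALSE]
    ir <- IRanges::IRanges(iv$start + 1L, iv$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    ov <- IRanges::findOverlaps(ir, red)
    sq <- scaffold_chars(g, sc)
    n <- lens[[sc]]
    for (j in seq_along(red)) {
      src <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]
      s0 <- BiocGenerics::start(red)[j] - 1L
      e0 <- BiocGenerics::end(red)[j]
      fl <- substr(sq, max(1L, s0 - flank + 1L), s0)
      fr <- substr(sq, e0 + 1L, min(n, e0 + flank))
      core <- substr(sq, s0 + 1L, e0)
      res[[length(res) + 1L]] <- data.frame(
        ucr_id = sprintf("%s:%s:%d-%d", g$species, sc, s0, e0),
        species = g$species, scaffold = sc, start = s0, end = e0,
        conserved_with = paste(sort(unique(iv$partner[src])), collapse = ","),
        n_elements = length(src),
        flank_left = fl, flank_right = fr,
        sequence_with_flanks = paste0(fl, core, fr),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_ucrs <- function(species) {
  data.frame(ucr_id = character(), species = character(),
             scaffold = character(), start = integer(), end = integer(),
             conserved_with = character(), n_elements = integer(),
             flank_left = character(), flank_right = character(),
             sequence_with_flanks = character(), stringsAsFactors = FALSE)
}

#' Call UCRs for every species from all pairwise match tables
#'
#' Convenience wrapper: projects every match table onto each species and
#' merges per species across all pairwise comparisons.
#'
#' @param genomes Named list of [genome] objects.
#' @param match_list List of match tables from [find_mems()].
#' @param flank Flank width in bp.
#' @return data.frame of UCRs for all species (rbind of per-species calls).
#' @export
call_ucrs <- function(genomes, match_list, flank = 50L) {
  res <- lapply(names(genomes), function(sp)
    merge_to_ucrs(project_matches(match_list, sp), genomes[[sp]], flank))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' UCR sequences (with flanks) as a DNAStringSet
#'
#' @param ucrs UCR table from [merge_to_ucrs()] / [call_ucrs()].
#' @return Named `DNAStringSet` keyed by `ucr_id`.
#' @export
ucr_sequences <- function(ucrs) {
  out <- Biostrings::DNAStringSet(ucrs$sequence_with_flanks)
  names(out) <- ucrs$ucr_id
  out
}
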