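#' Specification of a synthetic species genome
#'
#' @param species_id Short species label.
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_length Length of each scaffold in bp (recycled).
#' @param gc_content GC fraction in (0,1); 0 and 1 are allowed for boundary
#'   testing (sequence over `{A,T}` or `{G,C}` only).
#' @return A `species_spec` object.
#' @export
species_spec <- function(species_id, n_scaffolds = 1L, scaffold_length = 1e5,
                         gc_content = 0.5) {
  if (any(scaffold_length < 1)) stop("scaffold_length must be >= 1")
  if (n_scaffolds < 1) stop("n_scaffolds must be >= 1")
  if (gc_content < 0 || gc_content > 1) stop("gc_content must be in [0,1]")
  structure(list(species_id = species_id, n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length = as.integer(rep_len(scaffold_length, n_scaffolds)),
                 gc_content = gc_content),
            class = "species_spec")
}

#' Generate a random background genome
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`.
#' The simple zeroth-order model keeps k-mer statistics analytically
#' checkable downstream. Deterministic for a fixed seed.
#'
#' @param spec A [species_spec].
#' @param seed Integer seed.
#' @return A [genome] with no masked bases.
#' @export
generate_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "species_spec"))
  gc <- spec$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(sub_seed(seed, paste0("genome:", spec$species_id)), {
    vapply(spec$scaffold_length, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
  })
  names(seqs) <- sprintf("%s_scf%d", spec$species_id, seq_along(seqs))
  genome(seqs, spec$species_id)
}

#' Specification of one planted conserved element
#'
#' A planted element is a single master sequence written (replacement, not
#' insertion, so coordinates stay fixed) into two or more species genomes at
#' stated placements. Copies on the minus strand receive the reverse
#' complement of the master. Optional per-species substitution counts create
#' diverged copies; a species pair counts as an *exact* pair only when both
#' of its copies carry zero mutations.
#'
#' @param element_id Label.
#' @param length Element length in bp (>= 1).
#' @param placements Named list, one entry per species, each a list with
#'   `scaffold`, `start` (0-based) and `strand` (`"+"` or `"-"`).
#' @param mutations Named integer vector of per-species substitution counts
#'   (default 0 everywhere). Each count must be `< length`.
#' @return A `plant_spec` object.
#' @export
plant_spec <- function(element_id, length, placements, mutations = NULL) {
  if (length < 1) stop("element length must be >= 1")
  if (length(placements) < 2) stop("an element needs placements in >= 2 species")
  if (is.null(names(placements)) || anyDuplicated(names(placements)))
    stop("placements must be uniquely named by species")
  mut <- stats::setNames(rep(0L, length(placements)), names(placements))
  if (!is.null(mutations)) {
    if (any(mutations >= length)) stop("mutation count must be < element length")
    mut[names(mutations)] <- as.integer(mutations)
  }
  structure(list(element_id = element_id, length = as.integer(length),
                 placements = placements, mutations = mut),
            class = "plant_spec")
}

#' Plant conserved elements into genomes
#'
#' Writes each element's master sequence over the background at every stated
#' placement and returns the modified genomes with a truth table. By default
#' (`seal = TRUE`) the single background base adjacent to each end of a
#' placement is set so that it differs across all copies of the element
#' (complement-aware on the minus strand). Sealing makes the planted
#' coordinates the exact boundaries of the maximal match: with free random
#' flanks a match would extend past the planted boundary with probability
#' ~1/4 per side, so ground-truth coordinates would not be recoverable even
#' by a perfect detector.
#'
#' @param genomes Named list of [genome] objects (names = species).
#' @param plants List of [plant_spec] objects.
#' @param seed Integer seed (master sequences and mutation positions).
#' @param seal Force pairwise-distinct boundary bases across copies.
#' @return List with `genomes` (modified) and `truth`, a data.frame with one
#'   row per (element, species) copy: `element_id`, `species`, `scaffold`,
#'   `start`, `end` (0-based half-open), `strand`, `n_mutations`.
#' @export
plant_elements <- function(genomes, plants, seed, seal = TRUE) {
  stopifnot(is.list(genomes), all(vapply(genomes, inherits, TRUE, "genome")))
  # collision check: placements (plus 1 bp seal margin) must not overlap
  occ <- list()
  for (p in plants) for (sp in names(p$placements)) {
    pl <- p$placements[[sp]]
    lens <- scaffold_lengths(genomes[[sp]])
    if (!pl$scaffold %in% names(lens))
      stop(sprintf("element '%s': unknown scaffold '%s' in species '%s'",
                   p$element_id, pl$scaffold, sp))
    if (pl$start < 0 || pl$start + p$length > lens[[pl$scaffold]])
      stop(sprintf("element '%s' does not fit in %s:%s", p$element_id, sp,
                   pl$scaffold))
    key <- paste(sp, pl$scaffold)
    iv <- c(pl$start, pl$start + p$length, p$element_id)
    occ[[key]] <- c(occ[[key]], list(iv))
  }
  for (key in names(occ)) {
    ivs <- occ[[key]]
    if (length(ivs) > 1) {
      st <- vapply(ivs, function(v) as.integer(v[1]), 1L)
      en <- vapply(ivs, function(v) as.integer(v[2]), 1L)
      id <- vapply(ivs, function(v) v[3], "")
      o <- order(st)
      st <- st[o]; en <- en[o]; id <- id[o]
      bad <- which(st[-1] < en[-length(en)])
      if (length(bad))
        stop(sprintf("overlapping placements in %s: %s", key,
                     paste(unique(c(id[bad], id[bad + 1L])), collapse = ", ")))
    }
  }

  chars <- lapply(genomes, function(g)
    lapply(as.list(as.character(g$seqs)), function(s) strsplit(s, "")[[1]]))
  bases <- c("A", "C", "G", "T")
  truth <- list()

  with_seed(sub_seed(seed, "plant_elements"), {
    for (p in plants) {
      master <- sample(bases, p$length, replace = TRUE)
      sps <- names(p$placements)
      for (i in seq_along(sps)) {
        sp <- sps[i]; pl <- p$placements[[sp]]
        copy <- master
        nmut <- p$mutations[[sp]]
        if (nmut > 0) {
          pos <- sample.int(p$length, nmut)
          for (q in pos) copy[q] <- sample(setdiff(bases, copy[q]), 1)
        }
        if (identical(pl$strand, "-"))
          copy <- rev(chartr("ACGT", "TGCA", copy))
        s0 <- pl$start
        chars[[sp]][[pl$scaffold]][(s0 + 1):(s0 + p$length)] <- copy
        if (seal) {
          # orientation-left/right boundary letters, distinct per copy index
          Lb <- bases[(i - 1L) %% 4L + 1L]
          Rb <- bases[(i + 1L) %% 4L + 1L]
          scf <- chars[[sp]][[pl$scaffold]]
          n <- length(scf)
          if (identical(pl$strand, "-")) {
            if (s0 + p$length < n) scf[s0 + p$length + 1L] <- chartr("ACGT", "TGCA", Lb)
            if (s0 >= 1L) scf[s0] <- chartr("ACGT", "TGCA", Rb)
          } else {
            if (s0 >= 1L) scf[s0] <- Lb
            if (s0 + p$length < n) scf[s0 + p$length + 1L] <- Rb
          }
          chars[[sp]][[pl$scaffold]] <- scf
        }
        truth[[length(truth) + 1L]] <- data.frame(
          element_id = p$element_id, species = sp, scaffold = pl$scaffold,
          start = s0, end = s0 + p$length, strand = pl$strand,
          n_mutations = nmut, stringsAsFactors = FALSE)
      }
    }
  })

  out <- lapply(names(genomes), function(sp) {
    seqs <- vapply(chars[[sp]], paste, character(1), collapse = "")
    names(seqs) <- names(genomes[[sp]]$seqs)
    genome(seqs, sp)
  })
  names(out) <- names(genomes)
  list(genomes = out,
       truth = do.call(rbind, c(truth, list(stringsAsFactors = FALSE))))
}

#' Exact planted pairs from a truth table
#'
#' A pair of copies of one element in two species is exact when both copies
#' carry zero mutations; only exact pairs are discoverable as identical
#' matches.
#'
#' @param truth Truth table from [plant_elements()].
#' @param min_length Keep only elements at least this long.
#' @return data.frame with `element_id`, `species_a`, `species_b` and the
#'   copy coordinates of both sides.
#' @export
truth_exact_pairs <- function(truth, min_length = 1L) {
  res <- list()
  for (eid in unique(truth$element_id)) {
    rows <- truth[truth$element_id == eid & truth$n_mutations == 0L, ,
                  drop = FALSE]
    if (nrow(rows) < 2 || (rows$end[1] - rows$start[1]) < min_length) next
    cmb <- utils::combn(seq_len(nrow(rows)), 2)
    for (j in seq_len(ncol(cmb))) {
      a <- rows[cmb[1, j], ]; b <- rows[cmb[2, j], ]
      res[[length(res) + 1L]] <- data.frame(
        element_id = eid,
        species_a = a$species, scaffold_a = a$scaffold,
        start_a = a$start, end_a = a$end, strand_a = a$strand,
        species_b = b$species, scaffold_b = b$scaffold,
        start_b = b$start, end_b = b$end, strand_b = b$strand,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(element_id = character(), species_a = character(),
                      species_b = character(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Plant tandem repeats into a genome
#'
#' Each repeat is a random unit of `unit_length` bp repeated `copies` times,
#' written over the background at a random position (or at `positions` /
#' `units` if supplied) avoiding the `avoid` intervals and other repeats.
#'
#' @param g A [genome].
#' @param n_tandem Number of repeats to plant.
#' @param unit_length Unit length in bp.
#' @param copies Number of unit copies per repeat.
#' @param seed Integer seed.
#' @param avoid Optional data.frame (`scaffold`,`start`,`end`, 0-based
#'   half-open) of intervals repeats must not touch (e.g. planted elements).
#' @param positions,units Optional explicit placements: `positions` a
#'   data.frame (`scaffold`,`start`) and `units` a character vector of
#'   repeat units (recycled).
#' @param margin Unplanted gap demanded around each repeat (bp).
#' @return List with `genome` and `mask`, the truth intervals
#'   (0-based half-open data.frame with `kind = "tandem"`).
#' @export
plant_repeats <- function(g, n_tandem, unit_length = 4L, copies = 8L, seed = 1L,
                          avoid = NULL, positions = NULL, units = NULL,
                          margin = 10L) {
  stopifnot(inherits(g, "genome"))
  if (n_tandem == 0)
    return(list(genome = g, mask = interval_df()))
  span <- as.integer(unit_length * copies)
  lens <- scaffold_lengths(g)
  chars <- lapply(as.list(as.character(g$seqs)), function(s) strsplit(s, "")[[1]])

  taken <- list()  # per-scaffold occupied intervals (with margin)
  if (!is.null(avoid))
    for (j in seq_len(nrow(avoid))) {
      sc <- avoid$scaffold[j]
      taken[[sc]] <- rbind(taken[[sc]],
                           c(avoid$start[j] - margin, avoid$end[j] + margin))
    }
  collides <- function(sc, s, e) {
    tk <- taken[[sc]]
    !is.null(tk) && any(s < tk[, 2] & e > tk[, 1])
  }

  mask <- list()
  with_seed(sub_seed(seed, "plant_repeats"), {
    for (i in seq_len(n_tandem)) {
      unit <- if (!is.null(units)) {
        strsplit(units[(i - 1L) %% length(units) + 1L], "")[[1]]
      } else sample(c("A", "C", "G", "T"), unit_length, replace = TRUE)
      sp <- length(unit) * copies
      if (!is.null(positions)) {
        sc <- positions$scaffold[i]; s0 <- as.integer(positions$start[i])
        if (collides(sc, s0 - margin, s0 + sp + margin))
          stop(sprintf("repeat %d at %s:%d collides with an existing plant",
                       i, sc, s0))
      } else {
        placed <- FALSE
        for (try in 1:200) {
          sc <- sample(names(lens), 1, prob = lens)
          if (lens[[sc]] < sp + 2L) next
          s0 <- sample.int(lens[[sc]] - sp - 1L, 1)
          if (!collides(sc, s0 - margin, s0 + sp + margin)) { placed <- TRUE; break }
        }
        if (!placed) stop("could not place repeat without collision")
      }
      chars[[sc]][(s0 + 1):(s0 + sp)] <- rep_len(unit, sp)
      taken[[sc]] <- rbind(taken[[sc]], c(s0 - margin, s0 + sp + margin))
      mask[[length(mask) + 1L]] <- data.frame(
        scaffold = sc, start = s0, end = s0 + sp, kind = "tandem",
        stringsAsFactors = FALSE)
    }
  })
  seqs <- vapply(chars, paste, character(1), collapse = "")
  names(seqs) <- names(g$seqs)
  list(genome = genome(seqs, g$species),
       mask = do.call(rbind, c(mask, list(stringsAsFactors = FALSE))))
}

#' Generate synthetic gene annotations with protein-domain labels
#'
#' Places non-overlapping gene intervals on a genome and assigns each a set
#' of domain labels from a vocabulary. Under `placement_rule =
#' "near_elements"` a fraction of the genes are placed within
#' `near_distance` bp of supplied element intervals (emulating genes flanking
#' conserved elements); the rest are uniform.
#'
#' @param g A [genome].
#' @param n_genes Number of genes (>= 0).
#' @param domain_vocab Character vector of domain labels; must be non-empty
#'   when `domains_per_gene > 0`.
#' @param placement_rule `"uniform"` or `"near_elements"`.
#' @param seed Integer seed.
#' @param elements data.frame (`scaffold`,`start`,`end`) of element
#'   intervals, required for `"near_elements"`.
#' @param near_distance Max gap (bp) between a "near" gene and its element.
#' @param near_fraction Fraction of genes placed near elements.
#' @param gene_length Gene length in bp.
#' @param domains_per_gene Number of domain labels per gene (0 allowed).
#' @param near_domain Optional label always assigned to near-element genes
#'   (the planted enrichment signal); uniform genes draw from the rest of
#'   the vocabulary.
#' @return List with `genes` (data.frame `gene_id`,`species`,`scaffold`,
#'   `start`,`end`,`strand`, 0-based half-open) and `domains`
#'   (data.frame `gene_id`,`domain`).
#' @export
generate_annotations <- function(g, n_genes, domain_vocab,
                                 placement_rule = c("uniform", "near_elements"),
                                 seed = 1L, elements = NULL,
                                 near_distance = 1000L, near_fraction = 1.0,
                                 gene_length = 500L, domains_per_gene = 1L,
                                 near_domain = NULL) {
  placement_rule <- match.arg(placement_rule)
  if (n_genes == 0)
    return(list(genes = data.frame(gene_id = character(), species = character(),
                                   scaffold = character(), start = integer(),
                                   end = integer(), strand = character(),
                                   stringsAsFactors = FALSE),
                domains = data.frame(gene_id = character(), domain = character(),
                                     stringsAsFactors = FALSE)))
  if (domains_per_gene > 0 && length(domain_vocab) == 0)
    stop("domain vocabulary is empty but domains were requested")
  if (placement_rule == "near_elements" && is.null(elements))
    stop("'elements' required for near_elements placement")
  lens <- scaffold_lengths(g)
  taken <- list()
  collides <- function(sc, s, e) {
    tk <- taken[[sc]]
    !is.null(tk) && any(s < tk[, 2] & e > tk[, 1])
  }
  genes <- list(); doms <- list()
  with_seed(sub_seed(seed, "annotations"), {
    n_near <- if (placement_rule == "near_elements")
      round(near_fraction * n_genes) else 0L
    # guarantee every element gets at least one nearby gene when saturating
    elem_order <- if (n_near > 0)
      rep_len(sample.int(nrow(elements)), n_near) else integer()
    if (n_near > 0 && near_fraction >= 1 && nrow(elements) <= n_near)
      elem_order[seq_len(nrow(elements))] <- sample.int(nrow(elements))
    for (i in seq_len(n_genes)) {
      near <- i <= n_near
      placed <- FALSE
      for (try in 1:500) {
        if (near) {
          el <- elements[elem_order[i], ]
          sc <- el$scaffold
          gap <- sample.int(near_distance, 1) - 1L
          side <- sample(c(-1L, 1L), 1)
          s0 <- if (side > 0) el$end + gap else el$start - gap - gene_length
        } else {
          sc <- sample(names(lens), 1, prob = lens)
          s0 <- sample.int(max(lens[[sc]] - gene_length, 1L), 1) - 1L
        }
        e0 <- s0 + gene_length
        if (s0 >= 0 && e0 <= lens[[sc]] && !collides(sc, s0, e0)) {
          placed <- TRUE; break
        }
      }
      if (!placed) next  # skip unplaceable gene rather than fail
      taken[[sc]] <- rbind(taken[[sc]], c(s0, e0))
      gid <- sprintf("%s_gene%04d", g$species, i)
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, species = g$species, scaffold = sc, start = s0, end = e0,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
      if (domains_per_gene > 0) {
        dvs <- if (near && !is.null(near_domain)) {
          c(near_domain,
            sample(setdiff(domain_vocab, near_domain),
                   min(domains_per_gene - 1L,
                       length(setdiff(domain_vocab, near_domain)))))
        } else {
          vocab <- if (!is.null(near_domain))
            setdiff(domain_vocab, near_domain) else domain_vocab
          sample(vocab, min(domains_per_gene, length(vocab)))
        }
        for (dv in dvs)
          doms[[length(doms) + 1L]] <- data.frame(gene_id = gid, domain = dv,
                                                  stringsAsFactors = FALSE)
      }
    }
  })
  list(genes = do.call(rbind, c(genes, list(stringsAsFactors = FALSE))),
       domains = if (length(doms))
         do.call(rbind, c(doms, list(stringsAsFactors = FALSE)))
       else data.frame(gene_id = character(), domain = character(),
                       stringsAsFactors = FALSE))
}

#' Evolve aligned protein families along a tree under the JTT model
#'
#' Sites evolve independently under the JTT amino-acid substitution model
#' along a tree with branch lengths in expected substitutions per site
#' (simulation via [phangorn::simSeq]). Families are gap-free alignments,
#' one sequence per leaf.
#'
#' @param tree An [ape::phylo] tree with >= 3 leaves and non-negative branch
#'   lengths (zero allowed: no substitutions on that branch).
#' @param n_families Number of independent families.
#' @param sites_per_family Alignment columns per family.
#' @param seed Integer seed.
#' @return List of character matrices (leaves x sites, rownames = leaf
#'   labels), plus the generating tree in attribute `"tree"`.
#' @export
evolve_protein_families <- function(tree, n_families, sites_per_family, seed) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3) stop("tree must have >= 3 leaves")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  fams <- lapply(seq_len(n_families), function(i) {
    with_seed(sub_seed(seed, paste0("family:", i)), {
      sim <- phangorn::simSeq(tree, l = sites_per_family, type = "AA",
                              model = "JTT")
      m <- toupper(as.character(sim))
      m[order(rownames(m)), , drop = FALSE]
    })
  })
  attr(fams, "tree") <- tree
  fams
}
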