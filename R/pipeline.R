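#' Pipeline configuration
#'
#' Collects every stage threshold in one validated object. Defaults are the
#' standard study settings: 50 bp minimum match (30 bp for the short-element
#' track), 50 bp flanks, 100 kb gene window with a 10-gene minimum per
#' analyzed cluster, inflation 2.0, 5-mer embedding features, 8-mer motifs
#' against a 10 kb background flagged at p < 1e-4, 500 bootstrap replicates.
#'
#' @param species Either a named list of [genome] objects, or a `simulate`
#'   block (list with `n_species`, `scaffold_length`, `gc`, `n_elements`,
#'   `element_length`, `n_repeats`, and optional `n_genes`, `domain_vocab`).
#' @param min_length Minimum match length (bp).
#' @param flank Flank width (bp).
#' @param window Gene distance window (bp).
#' @param min_genes Minimum nearby genes per analyzed cluster.
#' @param inflation MCL inflation.
#' @param max_e E-value gate for similarity edges.
#' @param k_embed Embedding word size.
#' @param embed_dims Embedding dimensions.
#' @param k_motif Motif word size.
#' @param bg_length Background length (bp).
#' @param report_threshold Motif flag threshold.
#' @param bootstrap Bootstrap replicates for the phylogeny stage.
#' @param seed Global seed; all stage randomness derives from it via
#'   [sub_seed()].
#' @param outdir Output directory (created on run); `NULL` for no files.
#' @param genes,domains Optional gene and domain tables (see
#'   [cluster_domain_enrichment()]).
#' @param alignments Optional list of aligned protein family matrices for
#'   the phylogeny stage.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(species, min_length = 50L, flank = 50L,
                            window = 100000L, min_genes = 10L,
                            inflation = 2.0, max_e = 1e-5,
                            k_embed = 5L, embed_dims = 3L, k_motif = 8L,
                            bg_length = 10000L, report_threshold = 1e-4,
                            bootstrap = 500L, seed = 1L, outdir = NULL,
                            genes = NULL, domains = NULL, alignments = NULL) {
  thr <- c(min_length = min_length, flank = flank, window = window,
           min_genes = min_genes, inflation = inflation, k_embed = k_embed,
           embed_dims = embed_dims, k_motif = k_motif, bg_length = bg_length,
           bootstrap = bootstrap)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  structure(list(species = species, min_length = as.integer(min_length),
                 flank = as.integer(flank), window = as.integer(window),
                 min_genes = as.integer(min_genes), inflation = inflation,
                 max_e = max_e, k_embed = as.integer(k_embed),
                 embed_dims = as.integer(embed_dims),
                 k_motif = as.integer(k_motif),
                 bg_length = as.integer(bg_length),
                 report_threshold = report_threshold,
                 bootstrap = as.integer(bootstrap), seed = as.integer(seed),
                 outdir = outdir, genes = genes, domains = domains,
                 alignments = alignments),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the same fields as [pipeline_config()]; `species`
#' may be a named map of FASTA paths (loaded with [read_genome()]) or a
#' `simulate` block passed through.
#'
#' @param path YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$species) && is.list(y$species) &&
      all(vapply(y$species, is.character, TRUE))) {
    y$species <- mapply(function(p, nm) read_genome(p, species = nm),
                        y$species, names(y$species), SIMPLIFY = FALSE)
  }
  do.call(pipeline_config, y)
}

#' Run the full ultraconserved-element pipeline
#'
#' Executes mask -> find (all species pairs) -> remask -> merge ->
#' cluster -> embed -> enrich -> motif (and phylogeny when alignments are
#' given) and returns a manifest with per-stage counts, the seed, and file
#' checksums when `outdir` is set. Re-running with the same configuration
#' and seed is bit-identical.
#'
#' @param config A [pipeline_config].
#' @return List with `manifest` and `results` (per-stage tables:
#'   `genomes`, `masks`, `matches`, `ucrs`, `graph`, `clusters`,
#'   `embedding`, `enrichment`, `motifs`, `tree`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_stage <- function(fmt, ...)
    message(sprintf("[ultracons %5.1fs] %s",
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    sprintf(fmt, ...)))

  genomes <- config$species
  truth <- NULL
  if (!is.null(genomes$n_species)) {   # simulate block
    sim <- simulate_study(genomes, seed = config$seed)
    genomes <- sim$genomes
    truth <- sim$truth
    if (is.null(config$genes)) config$genes <- sim$genes
    if (is.null(config$domains)) config$domains <- sim$domains
    log_stage("simulated %d species, %d planted elements", length(genomes),
              length(unique(truth$element_id)))
  }
  if (length(genomes) < 2) stop("need at least 2 species")

  # -- masking --------------------------------------------------------------
  masks <- list(); masked <- list()
  for (sp in names(genomes)) {
    mk <- mask_genome(genomes[[sp]])
    masked[[sp]] <- mk$genome
    masks[[sp]] <- mk$intervals
    log_stage("masked %s: %d intervals", sp,
              if (is.null(mk$intervals)) 0L else nrow(mk$intervals))
  }

  # -- discovery + second-round masking -------------------------------------
  sps <- names(genomes)
  match_list <- list()
  for (i in seq_along(sps)[-length(sps)]) for (j in (i + 1):length(sps)) {
    m <- find_mems(masked[[sps[i]]], masked[[sps[j]]], config$min_length)
    m <- remask_matches(m, masked[[sps[i]]], config$min_length)
    match_list[[paste(sps[i], sps[j], sep = "-")]] <- m
    log_stage("%s vs %s: %d matches", sps[i], sps[j], nrow(m))
  }

  # -- merge to UCRs --------------------------------------------------------
  ucrs <- call_ucrs(masked, match_list, config$flank)
  log_stage("%d UCRs across %d species", nrow(ucrs),
            length(unique(ucrs$species)))

  graph <- NULL; clusters <- NULL; embedding <- NULL
  enrich <- NULL; motifs <- NULL
  if (nrow(ucrs) >= 2) {
    graph <- build_graph(ucr_sequences(ucrs), max_e = config$max_e)
    clusters <- mcl(graph, inflation = config$inflation)
    log_stage("%d clusters from %d nodes / %d edges",
              length(unique(clusters$cluster)), length(graph$nodes),
              nrow(graph$edges))
    prof <- kmer_profile(ucr_sequences(ucrs), config$k_embed)
    embedding <- mce_embed(prof, min(config$embed_dims, nrow(prof)))
    if (!is.null(config$genes) && nrow(config$genes)) {
      enrich <- cluster_domain_enrichment(clusters, ucrs, config$genes,
                                          config$domains, config$window,
                                          config$min_genes)
      log_stage("enrichment: %d (cluster, domain) rows",
                if (is.null(enrich)) 0L else nrow(enrich))
    }
    motifs <- cluster_motifs(clusters, ucrs, masked, config$k_motif,
                             config$bg_length,
                             report_threshold = config$report_threshold,
                             seed = config$seed)
    log_stage("motifs: %d rows, %d flagged", nrow(motifs),
              sum(motifs$flagged))
  }

  tree <- NULL
  if (!is.null(config$alignments)) {
    tree <- bootstrap_support(config$alignments, config$bootstrap,
                              seed = config$seed)
    log_stage("phylogeny: %d taxa, %d bootstrap replicates",
              length(tree$tip.label), config$bootstrap)
  }

  results <- list(genomes = masked, masks = masks, matches = match_list,
                  ucrs = ucrs, graph = graph, clusters = clusters,
                  embedding = embedding, enrichment = enrich,
                  motifs = motifs, tree = tree, truth = truth)

  files <- character(0)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    files <- write_pipeline_outputs(results, config)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ultracons")),
    seed = config$seed,
    n_species = length(genomes),
    n_pair_comparisons = length(match_list),
    thresholds = list(min_length = config$min_length, flank = config$flank,
                      window = config$window, min_genes = config$min_genes,
                      inflation = config$inflation, k_embed = config$k_embed,
                      k_motif = config$k_motif, bg_length = config$bg_length,
                      report_threshold = config$report_threshold),
    counts = list(
      mask_intervals = sum(vapply(masks, function(x)
        if (is.null(x)) 0L else nrow(x), 1L)),
      matches = sum(vapply(match_list, nrow, 1L)),
      ucrs = nrow(ucrs),
      clusters = if (is.null(clusters)) 0L
                 else length(unique(clusters$cluster)),
      enrichment_rows = if (is.null(enrich)) 0L else nrow(enrich),
      motif_rows = if (is.null(motifs)) 0L else nrow(motifs),
      motif_flagged = if (is.null(motifs)) 0L else sum(motifs$flagged)),
    checksums = as.list(files))
  if (!is.null(config$outdir)) {
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(manifest = manifest, results = results)
}

# Write standard per-stage outputs; returns named md5 checksums.
write_pipeline_outputs <- function(results, config) {
  od <- config$outdir
  paths <- character(0)
  for (sp in names(results$genomes)) {
    p <- file.path(od, paste0(sp, ".masked.fa"))
    write_genome(results$genomes[[sp]], p); paths <- c(paths, p)
    if (!is.null(results$masks[[sp]]) && nrow(results$masks[[sp]])) {
      p <- file.path(od, paste0(sp, ".mask.bed"))
      write_bed(results$masks[[sp]], p); paths <- c(paths, p)
    }
  }
  p <- file.path(od, "matches.tsv")
  write_matches(do.call(rbind, results$matches), p); paths <- c(paths, p)
  p <- file.path(od, "ucrs.tsv")
  utils::write.table(results$ucrs, p, sep = "\t", quote = FALSE,
                     row.names = FALSE); paths <- c(paths, p)
  if (nrow(results$ucrs)) {
    p <- file.path(od, "ucrs.fa")
    Biostrings::writeXStringSet(ucr_sequences(results$ucrs), p)
    paths <- c(paths, p)
  }
  for (nm in c("clusters", "enrichment", "motifs")) {
    if (!is.null(results[[nm]])) {
      p <- file.path(od, paste0(nm, ".tsv"))
      utils::write.table(results[[nm]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE); paths <- c(paths, p)
    }
  }
  if (!is.null(results$embedding)) {
    p <- file.path(od, "embedding.tsv")
    utils::write.table(
      data.frame(ucr_id = rownames(results$embedding$coords),
                 results$embedding$coords), p, sep = "\t", quote = FALSE,
      row.names = FALSE); paths <- c(paths, p)
  }
  if (!is.null(results$tree)) {
    p <- file.path(od, "species_tree.nwk")
    write_tree(results$tree, p); paths <- c(paths, p)
  }
  sums <- tools::md5sum(paths)
  names(sums) <- basename(paths)
  sums
}

#' Simulate a multi-species study with planted ground truth
#'
#' Builds the standard synthetic study: background genomes for each
#' species, planted exact conserved elements over random species subsets
#' and strands, planted tandem repeats (same unit planted in two species,
#' which repeat masking must remove), and gene annotations with a domain
#' planted near elements.
#'
#' @param block List with `n_species` (default 3), `scaffold_length`
#'   (default 1e6), `gc` (0.5), `n_elements` (50), `element_length` range
#'   (c(50, 300)), `n_repeats` (10), `repeat_unit` (5), `repeat_copies`
#'   (12), optional `n_genes` (0), `domain_vocab`, `near_domain`,
#'   `mutated_fraction` (0).
#' @param seed Integer seed.
#' @return List with `genomes`, `truth` (planted-element table),
#'   `repeat_masks` (per species), `genes`, `domains`.
#' @export
simulate_study <- function(block = list(), seed = 1L) {
  n_species <- block$n_species %||% 3L
  scaffold_length <- block$scaffold_length %||% 1e6
  gc <- block$gc %||% 0.5
  n_elements <- block$n_elements %||% 50L
  elen <- block$element_length %||% c(50L, 300L)
  n_repeats <- block$n_repeats %||% 10L
  repeat_unit <- block$repeat_unit %||% 5L
  repeat_copies <- block$repeat_copies %||% 12L
  n_genes <- block$n_genes %||% 0L
  sps <- sprintf("sp%s", LETTERS[seq_len(n_species)])

  genomes <- lapply(sps, function(sp)
    generate_genome(species_spec(sp, 1L, scaffold_length, gc),
                    seed = sub_seed(seed, sp)))
  names(genomes) <- sps

  # inter-element gap scaled to the scaffold so all elements always fit
  gap_cap <- min(15000L, as.integer(
    (scaffold_length - n_elements * (elen[2] + 210) - 300) / max(1, n_elements)))
  if (n_elements > 0 && gap_cap < 50)
    stop("scaffold_length too small for the requested elements")
  plants <- with_seed(sub_seed(seed, "plan"), {
    lens <- as.integer(round(stats::runif(n_elements, elen[1], elen[2])))
    # non-overlapping slots per species, generous margins
    slot <- list()
    for (sp in sps) slot[[sp]] <- 0L
    lapply(seq_len(n_elements), function(i) {
      k <- sample(2:n_species, 1)
      subset <- sort(sample(sps, k))
      placements <- list()
      for (sp in subset) {
        start <- slot[[sp]] + sample.int(gap_cap, 1) + 200L
        slot[[sp]] <<- start + lens[i]
        placements[[sp]] <- list(scaffold = paste0(sp, "_scf1"),
                                 start = start,
                                 strand = sample(c("+", "-"), 1))
      }
      mut <- NULL
      mf <- block$mutated_fraction %||% 0
      if (mf > 0 && stats::runif(1) < mf)
        mut <- stats::setNames(2L, subset[1])
      plant_spec(sprintf("el%03d", i), lens[i], placements, mutations = mut)
    })
  })
  planted <- plant_elements(genomes, plants, seed = sub_seed(seed, "plant"))
  genomes <- planted$genomes
  truth <- planted$truth

  repeat_masks <- list()
  if (n_repeats > 0) {
    units <- with_seed(sub_seed(seed, "units"), {
      vapply(seq_len(n_repeats), function(i)
        paste(sample(c("A", "C", "G", "T"), repeat_unit, replace = TRUE),
              collapse = ""), character(1))
    })
    for (sp in sps) {
      avoid <- truth[truth$species == sp, c("scaffold", "start", "end")]
      pr <- plant_repeats(genomes[[sp]], n_repeats,
                          unit_length = repeat_unit, copies = repeat_copies,
                          seed = sub_seed(seed, paste0("rep:", sp)),
                          avoid = avoid, units = units)
      genomes[[sp]] <- pr$genome
      repeat_masks[[sp]] <- pr$mask
    }
  }

  genes <- NULL; domains <- NULL
  if (n_genes > 0) {
    vocab <- block$domain_vocab %||% sprintf("PF%04d", 1:20)
    gl <- list(); dl <- list()
    for (sp in sps) {
      ann <- generate_annotations(
        genomes[[sp]], n_genes, vocab, placement_rule = "uniform",
        seed = sub_seed(seed, paste0("genes:", sp)))
      gl[[sp]] <- ann$genes; dl[[sp]] <- ann$domains
    }
    genes <- do.call(rbind, gl); rownames(genes) <- NULL
    domains <- do.call(rbind, dl); rownames(domains) <- NULL
  }

  list(genomes = genomes, truth = truth, repeat_masks = repeat_masks,
       genes = genes, domains = domains)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
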