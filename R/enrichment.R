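#' Genes near UCRs
#'
#' A gene is *nearby* a UCR when the minimal gap between the gene interval
#' and the UCR interval is at most `window` bp (overlap counts as distance
#' 0; a gene at exactly `window` bp is included). Matching is within
#' species and scaffold.
#'
#' @param ucrs UCR table ([merge_to_ucrs()] / [call_ucrs()]).
#' @param genes Gene table (`gene_id`,`species`,`scaffold`,`start`,`end`,
#'   0-based half-open).
#' @param window Distance window in bp (default 100 kb).
#' @return data.frame (`ucr_id`, `gene_id`, `distance`).
#' @export
find_nearby_genes <- function(ucrs, genes, window = 100000L) {
  if (!nrow(ucrs) || !nrow(genes))
    return(data.frame(ucr_id = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE))
  ug <- GenomicRanges::GRanges(
    paste(ucrs$species, ucrs$scaffold, sep = "|"),
    IRanges::IRanges(ucrs$start + 1L, ucrs$end))
  gg <- GenomicRanges::GRanges(
    paste(genes$species, genes$scaffold, sep = "|"),
    IRanges::IRanges(genes$start + 1L, genes$end))
  suppressWarnings({
    hits <- GenomicRanges::findOverlaps(ug, gg, maxgap = window)
    dd <- GenomicRanges::distance(ug[S4Vectors::queryHits(hits)],
                                  gg[S4Vectors::subjectHits(hits)])
  })
  keep <- !is.na(dd) & dd <= window
  data.frame(ucr_id = ucrs$ucr_id[S4Vectors::queryHits(hits)[keep]],
             gene_id = genes$gene_id[S4Vectors::subjectHits(hits)[keep]],
             distance = dd[keep], stringsAsFactors = FALSE)
}

#' Upper cumulative hypergeometric probability
#'
#' Probability of observing `d` or more genes carrying the domain among `g`
#' nearby genes drawn from a pool of `G` genes of which `D` carry the
#' domain: `P = sum_{i=d}^{min(D,g)} C(D,i) C(G-D,g-i) / C(G,g)`. Computed
#' via [stats::phyper] (log-space stable).
#'
#' @param G Pool size (total genes).
#' @param g Number of nearby genes drawn.
#' @param D Domain-carrying genes in the pool.
#' @param d Domain-carrying genes among the nearby set.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
hypergeom_upper <- function(G, g, D, d) {
  if (any(d > pmin(D, g)) || any(g > G) || any(D > G) || any(c(G, g, D, d) < 0))
    stop("invalid counts: require d <= min(D, g), g <= G, D <= G, all >= 0")
  stats::phyper(d - 1, D, G - D, g, lower.tail = FALSE)
}

#' Protein-domain enrichment of genes near each UCR cluster
#'
#' For every analyzed cluster and every domain present in the cluster's
#' species pool: `G` counts all genes of the species represented in the
#' cluster, `g` the unique genes within `window` of any member UCR, `D` and
#' `d` the genes carrying the domain in pool and nearby set (a gene carrying
#' the domain several times counts once, keeping `D <= G`). Clusters with
#' fewer than `min_genes` nearby genes are skipped with a message. Raw
#' p-values are primary (the display flag marks `p < 0.05` and `d >= 3`);
#' Benjamini-Hochberg adjusted values are added per cluster for convenience.
#'
#' @param clusters Cluster table from [mcl()] (`id` = ucr_id, `cluster`).
#' @param ucrs UCR table.
#' @param genes Gene table (see [find_nearby_genes()]).
#' @param domains data.frame (`gene_id`, `domain`).
#' @param window Distance window in bp (default 100 kb).
#' @param min_genes Minimum nearby genes for a cluster to be analyzed
#'   (default 10).
#' @return data.frame (`cluster`,`domain`,`G`,`g`,`D`,`d`,`p_value`,
#'   `adjusted_p`,`flagged`), sorted by cluster then p-value.
#' @export
cluster_domain_enrichment <- function(clusters, ucrs, genes, domains,
                                      window = 100000L, min_genes = 10L) {
  nearby <- find_nearby_genes(ucrs, genes, window)
  rows <- list()
  for (cl in sort(unique(clusters$cluster))) {
    member_ids <- clusters$id[clusters$cluster == cl]
    members <- ucrs[ucrs$ucr_id %in% member_ids, , drop = FALSE]
    pool_species <- unique(members$species)
    pool <- genes[genes$species %in% pool_species, , drop = FALSE]
    G <- nrow(pool)
    near_genes <- unique(nearby$gene_id[nearby$ucr_id %in% member_ids])
    near_genes <- intersect(near_genes, pool$gene_id)
    g <- length(near_genes)
    if (g < min_genes) {
      message(sprintf("cluster %s skipped: %d nearby genes < min_genes = %d",
                      cl, g, min_genes))
      next
    }
    dmap <- unique(domains[domains$gene_id %in% pool$gene_id, , drop = FALSE])
    if (!nrow(dmap)) next
    for (dom in sort(unique(dmap$domain))) {
      carriers <- unique(dmap$gene_id[dmap$domain == dom])
      D <- length(carriers)
      d <- length(intersect(carriers, near_genes))
      p <- hypergeom_upper(G, g, D, d)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, domain = dom, G = G, g = g, D = D, d = d,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cluster = integer(), domain = character(), G = integer(),
                      g = integer(), D = integer(), d = integer(),
                      p_value = double(), adjusted_p = double(),
                      flagged = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$adjusted_p <- NA_real_
  for (cl in unique(out$cluster)) {
    sel <- out$cluster == cl
    out$adjusted_p[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
  }
  out$flagged <- out$p_value < 0.05 & out$d >= 3
  out <- out[order(out$cluster, out$p_value, out$domain), , drop = FALSE]
  rownames(out) <- NULL
  out
}
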