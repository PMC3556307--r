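#' Write gene annotations to GFF3
#'
#' Genes are written as `gene` features with 1-based inclusive coordinates
#' per the GFF3 standard; domain labels are attached as a `domains`
#' attribute (comma-joined).
#'
#' @param genes Gene table (`gene_id`,`species`,`scaffold`,`start`,`end`,
#'   `strand`, 0-based half-open).
#' @param domains Optional data.frame (`gene_id`,`domain`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path, domains = NULL) {
  gr <- GenomicRanges::GRanges(
    genes$scaffold, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  if (!is.null(domains) && nrow(domains)) {
    dd <- vapply(genes$gene_id, function(g)
      paste(sort(domains$domain[domains$gene_id == g]), collapse = ","),
      character(1))
    S4Vectors::mcols(gr)$domains <- unname(dd)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Reads `gene` features and returns the 0-based half-open gene table used
#' by the enrichment stage.
#'
#' @param path GFF3 file.
#' @param species Species label to attach.
#' @return Gene table data.frame.
#' @export
read_genes_gff3 <- function(path, species) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  data.frame(gene_id = as.character(gr$ID), species = species,
             scaffold = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Read a gene-to-domain map from TSV
#'
#' Two-column TSV (`gene_id`, `domain`), no header required.
#'
#' @param path TSV file.
#' @return data.frame (`gene_id`,`domain`).
#' @export
read_domain_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("domain map needs two columns: gene_id, domain")
  stats::setNames(df[, 1:2], c("gene_id", "domain"))
}
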