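# Pre-processing: restrict to protein-coding genes, build the exon
# knowledgebase and the annotated exon-exon adjacency knowledgebase, and
# keep only SNPs that fall inside coding exons.

#' Keep only protein-coding genes
#'
#' A gene counts as protein-coding when it maps to at least one protein,
#' either through `protein_ids` on the model (e.g. `protein_id` GFF3
#' attributes) or through an optional external gene-to-protein table.
#'
#' @param genes List of [gene_model()] objects.
#' @param protein_map Optional `data.frame` with columns `gene_id`,
#'   `protein_id`; entries are merged into the models before filtering.
#' @return The coding subset of `genes`, order preserved, with merged
#'   protein ids.
#' @export
filter_coding_genes <- function(genes, protein_map = NULL) {
  if (!is.null(protein_map)) {
    stopifnot(all(c("gene_id", "protein_id") %in% names(protein_map)))
    extra <- split(as.character(protein_map$protein_id),
                   as.character(protein_map$gene_id))
    genes <- lapply(genes, function(g) {
      if (g$gene_id %in% names(extra))
        g$protein_ids <- unique(c(g$protein_ids, extra[[g$gene_id]]))
      g
    })
  }
  keep <- vapply(genes, function(g) length(g$protein_ids) > 0L, logical(1))
  if (!any(keep)) message("filter_coding_genes: no coding genes remain")
  genes[keep]
}

#' Build the coding-exon knowledgebase
#'
#' All distinct coding exons across the (coding-filtered) genes, in
#' deterministic order.
#'
#' @param genes List of [gene_model()] objects.
#' @return `data.frame` with columns `exon_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `frame_offset`, ordered by
#'   (chrom, start, end, strand, gene_id).
#' @export
build_exon_kb <- function(genes) {
  if (length(genes) == 0L)
    return(data.frame(exon_id = character(0), gene_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame_offset = integer(0)))
  kb <- do.call(rbind, lapply(genes, function(g)
    cbind(g$exons, gene_id = g$gene_id, stringsAsFactors = FALSE)))
  kb <- kb[!duplicated(kb[c("gene_id", "exon_id")]), ]
  kb <- kb[order(kb$chrom, kb$start, kb$end, kb$strand, kb$gene_id), ]
  rownames(kb) <- NULL
  kb[c("exon_id", "gene_id", "chrom", "start", "end", "strand",
       "frame_offset")]
}

#' Build the annotated exon-exon adjacency knowledgebase
#'
#' The set of ordered (5', 3') coding-exon pairs that occur consecutively
#' in any annotated transcript of any gene.
#'
#' @param genes List of [gene_model()] objects.
#' @return `data.frame` of class `adjacency_kb` with columns `gene_id`,
#'   `exon5`, `exon3`, unique rows in deterministic order.
#' @export
build_exon_comb_kb <- function(genes) {
  rows <- list()
  for (g in genes) {
    for (ex_ids in g$transcripts) {
      n <- length(ex_ids)
      if (n >= 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g$gene_id, exon5 = ex_ids[-n], exon3 = ex_ids[-1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  kb <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(gene_id = character(0), exon5 = character(0),
               exon3 = character(0))
  kb <- kb[order(kb$gene_id, kb$exon5, kb$exon3), ]
  rownames(kb) <- NULL
  class(kb) <- c("adjacency_kb", "data.frame")
  kb
}

#' Keep only SNPs inside annotated coding exons
#'
#' Containment is inclusive on both exon ends. When an assembly is
#' supplied, SNPs whose reference allele disagrees with the genome are
#' kept but flagged (`ref_mismatch`) and a warning is emitted: variation
#' and assembly releases can legitimately disagree, and variant
#' application substitutes the alternate allele regardless.
#'
#' @param snps SNP `data.frame` as returned by [read_snps()].
#' @param exon_kb Exon knowledgebase from [build_exon_kb()].
#' @param assembly Optional `genome_assembly` for reference-allele checks.
#' @return Filtered SNP `data.frame` (with `ref_mismatch` column when
#'   `assembly` is given).
#' @export
filter_exonic_snps <- function(snps, exon_kb, assembly = NULL) {
  if (nrow(snps) == 0L || nrow(exon_kb) == 0L) return(snps[0, , drop = FALSE])
  ex_gr <- GenomicRanges::GRanges(
    exon_kb$chrom, IRanges::IRanges(exon_kb$start, exon_kb$end))
  snp_gr <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  hit <- GenomicRanges::countOverlaps(snp_gr, ex_gr, type = "within") > 0L
  out <- snps[hit, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(assembly) && nrow(out) > 0L) {
    genome_base <- mapply(function(ch, p) substr(assembly[[ch]], p, p),
                          out$chrom, out$pos, USE.NAMES = FALSE)
    out$ref_mismatch <- genome_base != out$ref
    if (any(out$ref_mismatch))
      warning(sum(out$ref_mismatch),
              " SNP(s) disagree with the genome reference allele; kept")
  }
  out
}

#' Summarise pre-processing
#'
#' @param genes_in,genes_coding,snps_in,snps_exonic Counts.
#' @return A `preprocess_report` list.
#' @export
preprocess_report <- function(genes_in, genes_coding, snps_in, snps_exonic) {
  stopifnot(genes_coding <= genes_in, snps_exonic <= snps_in)
  structure(list(genes_in = genes_in, genes_coding = genes_coding,
                 snps_in = snps_in, snps_exonic = snps_exonic),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("<preprocess_report> genes %d -> %d coding; SNPs %d -> %d exonic\n",
              x$genes_in, x$genes_coding, x$snps_in, x$snps_exonic))
  invisible(x)
}
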