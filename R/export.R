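# FASTA and TSV writers with a fixed header scheme, plus dataset
# presets.

#' Dataset presets
#'
#' * `PEPPI_KB` - annotated regions only (EXON_KB, E_E_KB), wild type.
#' * `PEPPI_without_SNP` - all five region types, wild type only.
#' * `PEPPI_with_SNP` - all five region types plus SNP variant peptides.
#'
#' @param preset Preset name.
#' @return List with `enabled_region_types` and `include_variants`.
#' @export
dataset_preset <- function(preset = c("PEPPI_with_SNP", "PEPPI_without_SNP",
                                      "PEPPI_KB")) {
  preset <- match.arg(preset)
  switch(preset,
    PEPPI_KB = list(enabled_region_types = c("EXON_KB", "E_E_KB"),
                    include_variants = FALSE),
    PEPPI_without_SNP = list(enabled_region_types = REGION_TYPES,
                             include_variants = FALSE),
    PEPPI_with_SNP = list(enabled_region_types = REGION_TYPES,
                          include_variants = TRUE))
}

.region_loc <- function(r) {
  iv <- sprintf("%d-%d", r$segments$start, r$segments$end)
  sprintf("%s:%s(%s)", r$segments$chrom[1L], paste(iv, collapse = "|"),
          r$segments$strand[1L])
}

#' Write peptides as an annotated FASTA database
#'
#' One record per peptide, in peptide-id order, 60-column wrapping, with
#' the header
#' `>{peptide_id} REG={region_id} TYPE={type} GENE={gene} ORF={orf}
#' SNP={snp_id|-} LOC={chrom}:{start5}-{end5}[|{start3}-{end3}]({strand})`.
#'
#' @param peptides Peptide `data.frame` from [generate_peptides()].
#' @param regions Region list from [generate_all()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(peptides, regions, path) {
  reg_by_id <- stats::setNames(regions,
                               vapply(regions, `[[`, "", "region_id"))
  peptides <- peptides[order(peptides$peptide_id), , drop = FALSE]
  headers <- vapply(seq_len(nrow(peptides)), function(i) {
    r <- reg_by_id[[peptides$region_id[i]]]
    sprintf("%s REG=%s TYPE=%s GENE=%s ORF=%d SNP=%s LOC=%s",
            peptides$peptide_id[i], r$region_id, r$region_type, r$gene_id,
            r$orf,
            ifelse(is.na(peptides$snp_id[i]), "-", peptides$snp_id[i]),
            .region_loc(r))
  }, "")
  aa <- Biostrings::AAStringSet(peptides$sequence)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write the result tables
#'
#' Writes `regions.tsv`, `peptides.tsv`, `peptide_snp_map.tsv` and
#' `peptide_protein_hits.tsv` (header-only when empty) in deterministic
#' row order, and logs a per-type region/peptide count line in the shape
#' of a database-content statistics table.
#'
#' @param out_dir Output directory (created if needed).
#' @param regions Region list.
#' @param peptides Peptide `data.frame`.
#' @param snp_map Peptide-SNP map `data.frame`.
#' @param hits Optional peptide-protein hit `data.frame`.
#' @param rejections Optional region rejection log, written as
#'   `region_rejections.tsv`.
#' @return Invisibly, named vector of written paths.
#' @export
write_tables <- function(out_dir, regions, peptides, snp_map, hits = NULL,
                         rejections = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rt <- regions_table(regions)
  paths <- c(regions = file.path(out_dir, "regions.tsv"),
             peptides = file.path(out_dir, "peptides.tsv"),
             snp_map = file.path(out_dir, "peptide_snp_map.tsv"),
             hits = file.path(out_dir, "peptide_protein_hits.tsv"))
  .write_tsv(rt, paths["regions"])
  .write_tsv(peptides, paths["peptides"])
  .write_tsv(snp_map, paths["snp_map"])
  .write_tsv(if (is.null(hits))
    data.frame(peptide_id = character(0), protein_id = character(0),
               offset = integer(0)) else hits, paths["hits"])
  if (!is.null(rejections)) {
    paths["rejections"] <- file.path(out_dir, "region_rejections.tsv")
    .write_tsv(rejections, paths["rejections"])
  }
  # per-type counts, one line per region type
  wild <- peptides[peptides$is_wild_type, , drop = FALSE]
  vari <- peptides[!peptides$is_wild_type, , drop = FALSE]
  reg_type <- stats::setNames(rt$region_type, rt$region_id)
  for (ty in REGION_TYPES) {
    n_reg <- sum(rt$region_type == ty)
    n_wild <- sum(reg_type[wild$region_id] == ty)
    n_var <- sum(reg_type[vari$region_id] == ty)
    message(sprintf("%-8s regions/wild peptides: %6d  SNP peptides: %6d  all: %6d",
                    ty, n_reg, n_var, n_wild + n_var))
  }
  invisible(paths)
}
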