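# SNP variant peptides: place exonic SNPs onto region cDNA, substitute,
# re-translate under the region's own protocol, and keep non-synonymous
# valid peptides (one SNP per variant peptide).

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

#' Place SNPs onto a peptide region
#'
#' A SNP is placeable when its genomic position falls inside an exon-role
#' segment of the region (intron segments never receive SNPs). The local
#' 1-based cDNA position is computed through the segment offsets; for
#' minus-strand regions the alleles are complemented into region
#' orientation.
#'
#' @param region A `peptide_region`.
#' @param snps SNP `data.frame` (exonic-filtered; one row per alt
#'   allele).
#' @return `data.frame` with columns `snp_id`, `local_pos`,
#'   `genomic_pos`, `ref_local`, `alt_local`, ordered by (local_pos,
#'   alt_local).
#' @export
place_snps <- function(region, snps) {
  seg <- region$segments
  seg_len <- seg$end - seg$start + 1L
  offsets <- c(0L, cumsum(seg_len))[seq_len(nrow(seg))]
  rows <- list()
  for (k in seq_len(nrow(seg))) {
    if (!seg$role[k] %in% c("exon", "exon5", "exon3")) next
    hit <- snps$chrom == seg$chrom[k] & snps$pos >= seg$start[k] &
      snps$pos <= seg$end[k]
    if (!any(hit)) next
    s <- snps[hit, , drop = FALSE]
    if (seg$strand[k] == "+") {
      local <- offsets[k] + (s$pos - seg$start[k]) + 1L
      ref_l <- s$ref; alt_l <- s$alt
    } else {
      local <- offsets[k] + (seg$end[k] - s$pos) + 1L
      ref_l <- .complement(s$ref); alt_l <- .complement(s$alt)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = s$snp_id, local_pos = as.integer(local), genomic_pos = s$pos,
      ref_local = ref_l, alt_local = alt_l, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(0), local_pos = integer(0),
               genomic_pos = integer(0), ref_local = character(0),
               alt_local = character(0))
  out <- out[order(out$local_pos, out$alt_local, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply one SNP placement to a region
#'
#' Substitutes the alternate base at the local cDNA position, re-runs the
#' region type's peptide estimation protocol and classifies the outcome.
#' Variants whose peptide equals the wild type are synonymous; variants
#' failing the protocol (e.g. an introduced non-tolerated stop) are
#' invalid. A truncating but sequence-changing variant is kept: the
#' altered sequence is observable by MS.
#'
#' @param region A `peptide_region`.
#' @param placement One row of [place_snps()] output.
#' @param min_peptide_len Minimum retained peptide length.
#' @return List with `status` (`"ok"`, `"synonymous"` or
#'   `"invalid_peptide"`) and, when ok: `sequence`, `snp_id`,
#'   `local_pos`, `genomic_pos`, `nt_change`, `aa_pos`, `aa_ref`,
#'   `aa_alt`.
#' @export
apply_snp <- function(region, placement, min_peptide_len = 1L) {
  p <- placement$local_pos
  stopifnot(p >= 1L, p <= nchar(region$cdna))
  have <- substr(region$cdna, p, p)
  if (have != placement$ref_local)
    warning(sprintf("SNP %s: region cDNA has %s at local position %d, expected %s",
                    placement$snp_id, have, p, placement$ref_local))
  cdna2 <- region$cdna
  substr(cdna2, p, p) <- placement$alt_local
  est <- estimate_peptide(cdna2, region$orf, region$region_type,
                          region$junction_offset, min_peptide_len)
  if (!est$ok) return(list(status = "invalid_peptide", reason = est$reason))
  if (identical(est$peptide, region$wild_peptide))
    return(list(status = "synonymous"))
  aa_pos <- (p - 1L - region$orf) %/% 3L + 1L
  wild <- region$wild_peptide
  aa_ref <- if (aa_pos >= 1L && aa_pos <= nchar(wild))
    substr(wild, aa_pos, aa_pos) else "*"
  aa_alt <- if (aa_pos >= 1L && aa_pos <= nchar(est$peptide))
    substr(est$peptide, aa_pos, aa_pos) else "*"
  list(status = "ok", sequence = est$peptide, snp_id = placement$snp_id,
       local_pos = p, genomic_pos = placement$genomic_pos,
       nt_change = paste0(placement$ref_local, ">", placement$alt_local),
       aa_pos = aa_pos, aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Generate wild-type and SNP variant peptides for all regions
#'
#' For each region, emits the wild-type peptide entry first, then one
#' independently applied candidate per (SNP, alternate allele) placement
#' (single-SNP variants only; no haplotype combinations). Peptide ids are
#' assigned serially `PEP000000001, ...` in region order, wild type
#' first, then placements by local position and allele.
#'
#' @param regions List of `peptide_region` objects with assigned ids.
#' @param snps Exonic-filtered SNP `data.frame`.
#' @param include_variants Generate SNP variants (`FALSE` = wild type
#'   only).
#' @param min_peptide_len Minimum retained peptide length.
#' @return List with `peptides` (`data.frame`: peptide_id, region_id,
#'   sequence, is_wild_type, snp_id), `snp_map` (`data.frame`:
#'   peptide_id, snp_id, local_pos, genomic_pos, nt_change, aa_change)
#'   and `rejections` (`data.frame` of discarded variant candidates).
#' @export
generate_peptides <- function(regions, snps, include_variants = TRUE,
                              min_peptide_len = 1L) {
  peptides <- list()
  snp_map <- list()
  rejections <- list()
  serial <- 0L
  next_id <- function() {
    serial <<- serial + 1L
    sprintf("PEP%09d", serial)
  }
  for (region in regions) {
    peptides[[length(peptides) + 1L]] <- data.frame(
      peptide_id = next_id(), region_id = region$region_id,
      sequence = region$wild_peptide, is_wild_type = TRUE,
      snp_id = NA_character_, stringsAsFactors = FALSE)
    if (!include_variants) next
    placements <- place_snps(region, snps)
    for (r in seq_len(nrow(placements))) {
      res <- apply_snp(region, placements[r, ], min_peptide_len)
      if (res$status == "ok") {
        pid <- next_id()
        peptides[[length(peptides) + 1L]] <- data.frame(
          peptide_id = pid, region_id = region$region_id,
          sequence = res$sequence, is_wild_type = FALSE,
          snp_id = res$snp_id, stringsAsFactors = FALSE)
        snp_map[[length(snp_map) + 1L]] <- data.frame(
          peptide_id = pid, snp_id = res$snp_id, local_pos = res$local_pos,
          genomic_pos = res$genomic_pos, nt_change = res$nt_change,
          aa_change = sprintf("%s%d%s", res$aa_ref, res$aa_pos, res$aa_alt),
          stringsAsFactors = FALSE)
      } else {
        rejections[[length(rejections) + 1L]] <- data.frame(
          region_id = region$region_id, snp_id = placements$snp_id[r],
          local_pos = placements$local_pos[r], status = res$status,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty_pep <- data.frame(peptide_id = character(0), region_id = character(0),
                          sequence = character(0), is_wild_type = logical(0),
                          snp_id = character(0))
  empty_map <- data.frame(peptide_id = character(0), snp_id = character(0),
                          local_pos = integer(0), genomic_pos = integer(0),
                          nt_change = character(0), aa_change = character(0))
  empty_rej <- data.frame(region_id = character(0), snp_id = character(0),
                          local_pos = integer(0), status = character(0))
  out <- list(
    peptides = if (length(peptides)) do.call(rbind, peptides) else empty_pep,
    snp_map = if (length(snp_map)) do.call(rbind, snp_map) else empty_map,
    rejections = if (length(rejections)) do.call(rbind, rejections) else
      empty_rej)
  rownames(out$peptides) <- NULL
  rownames(out$snp_map) <- NULL
  rownames(out$rejections) <- NULL
  out
}
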