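# Independent brute-force enumeration oracle. Re-derives the region
# generation protocols with its own sequence handling, codon table and
# codon-by-codon scan, sharing no code with the main generators, so the
# two implementations can cross-validate each other.

.ORC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

.orc_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

.orc_seq <- function(assembly, chrom, a, b, strand) {
  s <- substr(assembly[[chrom]], a, b)
  if (strand == "-") s <- .orc_revcomp(s) else s
}

# codon-by-codon scan applying one region type's validation protocol;
# returns the peptide string or NA if the candidate is invalid
.orc_estimate <- function(cdna, orf, type, joff0, min_len) {
  n <- nchar(cdna)
  aas <- character(0)
  n_codons <- (n - orf) %/% 3L
  if (n_codons < 1L) return(NA_character_)
  stopped <- FALSE
  for (k in seq_len(n_codons)) {
    codon <- substr(cdna, orf + 3L * (k - 1L) + 1L, orf + 3L * k)
    aa <- if (codon %in% names(.ORC_CODE)) unname(.ORC_CODE[codon]) else "X"
    if (aa == "*") {
      if (type %in% c("E_I_TH", "E_E_TH")) {
        if (orf + 3L * k - 1L < joff0) return(NA_character_)  # in 5' exon
        stopped <- TRUE
        break                                                  # truncate
      } else {
        if (k == n_codons) { stopped <- TRUE; break }          # C-terminus
        return(NA_character_)                                  # internal
      }
    }
    aas <- c(aas, aa)
  }
  pep <- paste(aas, collapse = "")
  if (grepl("X", pep, fixed = TRUE)) return(NA_character_)
  if (nchar(pep) < min_len) return(NA_character_)
  if (!is.na(joff0)) {
    first0 <- orf
    last0 <- orf + 3L * nchar(pep) - 1L
    if (!(first0 < joff0 && last0 >= joff0)) return(NA_character_)
  }
  pep
}

.orc_tail <- function(iv, strand, k) {  # last k bases in tx orientation
  take <- min(k, iv[2] - iv[1] + 1L)
  if (strand == "+") c(iv[2] - take + 1L, iv[2]) else c(iv[1], iv[1] + take - 1L)
}
.orc_head <- function(iv, strand, k) {  # first k bases in tx orientation
  take <- min(k, iv[2] - iv[1] + 1L)
  if (strand == "+") c(iv[1], iv[1] + take - 1L) else c(iv[2] - take + 1L, iv[2])
}

#' Brute-force enumeration oracle for one gene
#'
#' Exhaustively enumerates all candidate regions of a (small) gene and
#' applies the five validation protocols literally, using an
#' implementation wholly separate from [generate_all()]. Intended for
#' equivalence testing.
#'
#' @param gene A [gene_model()].
#' @param assembly A `genome_assembly`.
#' @param adjacency Adjacency knowledgebase from [build_exon_comb_kb()].
#' @param flank_nt Flank size (default 120).
#' @param min_peptide_len Minimum peptide length (default 1).
#' @return `data.frame` with one row per surviving region: `region_type`,
#'   `loc` (`start-end` per segment, `|`-joined), `orf`, `peptide`.
#' @export
oracle_enumerate <- function(gene, assembly, adjacency, flank_nt = 120L,
                             min_peptide_len = 1L) {
  ex <- gene$exons
  n <- nrow(ex)
  strand <- gene$strand
  rows <- list()
  emit <- function(type, ivs, orf, pep) {
    rows[[length(rows) + 1L]] <<- data.frame(
      region_type = type,
      loc = paste(vapply(ivs, function(iv) sprintf("%d-%d", iv[1], iv[2]),
                         ""), collapse = "|"),
      orf = orf, peptide = pep, stringsAsFactors = FALSE)
  }
  try_junction <- function(type, iv5, iv3, orfs) {
    s5 <- .orc_seq(assembly, gene$chrom, iv5[1], iv5[2], strand)
    s3 <- .orc_seq(assembly, gene$chrom, iv3[1], iv3[2], strand)
    cdna <- paste0(s5, s3)
    for (orf in orfs) {
      pep <- .orc_estimate(cdna, orf, type, nchar(s5), min_peptide_len)
      if (!is.na(pep)) emit(type, list(iv5, iv3), orf, pep)
    }
  }
  # exonic regions
  for (i in seq_len(n)) {
    iv <- c(ex$start[i], ex$end[i])
    cdna <- .orc_seq(assembly, gene$chrom, iv[1], iv[2], strand)
    pep <- .orc_estimate(cdna, ex$frame_offset[i], "EXON_KB", NA,
                         min_peptide_len)
    if (!is.na(pep)) emit("EXON_KB", list(iv), ex$frame_offset[i], pep)
  }
  iv_of <- function(eid) {
    r <- ex[ex$exon_id == eid, ]
    c(r$start, r$end)
  }
  # annotated junctions
  adj_g <- adjacency[adjacency$gene_id == gene$gene_id, , drop = FALSE]
  for (r in seq_len(nrow(adj_g))) {
    iv5e <- iv_of(adj_g$exon5[r])
    iv3e <- iv_of(adj_g$exon3[r])
    len5 <- iv5e[2] - iv5e[1] + 1L
    frame5 <- ex$frame_offset[ex$exon_id == adj_g$exon5[r]]
    trim <- len5 - min(flank_nt, len5)
    orf <- ((frame5 - trim) %% 3L + 3L) %% 3L
    try_junction("E_E_KB", .orc_tail(iv5e, strand, flank_nt),
                 .orc_head(iv3e, strand, flank_nt), orf)
  }
  # exon-intron and intron-exon (adjacent gene-level introns only)
  gap <- function(i) {   # intron after exon i in transcription order
    if (strand == "+") c(ex$end[i] + 1L, ex$start[i + 1L] - 1L)
    else c(ex$end[i + 1L] + 1L, ex$start[i] - 1L)
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      iv_int <- gap(i)
      if (iv_int[1] > iv_int[2]) next
      try_junction("E_I_TH",
                   .orc_tail(c(ex$start[i], ex$end[i]), strand, flank_nt),
                   .orc_head(iv_int, strand, flank_nt), 0:2)
      try_junction("I_E_TH", .orc_tail(iv_int, strand, flank_nt),
                   .orc_head(c(ex$start[i + 1L], ex$end[i + 1L]), strand,
                             flank_nt), 0:2)
    }
    # hypothetical exon pairs
    adj_keys <- paste(adj_g$exon5, adj_g$exon3)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (ex$start[i] <= ex$end[j] && ex$start[j] <= ex$end[i]) next
        if (paste(ex$exon_id[i], ex$exon_id[j]) %in% adj_keys) next
        try_junction("E_E_TH",
                     .orc_tail(c(ex$start[i], ex$end[i]), strand, flank_nt),
                     .orc_head(c(ex$start[j], ex$end[j]), strand, flank_nt),
                     0:2)
      }
    }
  }
  if (!length(rows))
    return(data.frame(region_type = character(0), loc = character(0),
                      orf = integer(0), peptide = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$region_type, out$loc, out$orf), ]
  rownames(out) <- NULL
  out
}
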