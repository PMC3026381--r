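# Hand-specified single-gene locus builder for protocol-level tests.
# Exon sequences are given in transcription orientation; phases are
# chained from the cumulative coding length. Returns the assembly, the
# gene model and its annotated adjacency table.
locus <- function(exon_seqs, intron_seqs = NULL, strand = "+",
                  gene_id = "g1", chrom = "chrT", flank = 25L,
                  transcripts = NULL) {
  n <- length(exon_seqs)
  if (is.null(intron_seqs) && n > 1L)
    intron_seqs <- replicate(n - 1L, paste(
      rep(c("C", "A", "T"), length.out = 21L), collapse = ""))
  lens <- nchar(exon_seqs)
  cum <- c(0L, cumsum(lens))
  phases <- (3L - cum[seq_len(n)] %% 3L) %% 3L
  pieces <- character(0)
  for (i in seq_len(n)) {
    pieces <- c(pieces, exon_seqs[i])
    if (i < n) pieces <- c(pieces, intron_seqs[i])
  }
  pad <- function(k) paste(rep("T", k), collapse = "")
  genomic <- if (strand == "+") pieces else
    rev(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(pieces))))
  chrom_seq <- paste0(pad(flank), paste(genomic, collapse = ""), pad(flank))
  # locate exons
  offs <- flank + c(0L, cumsum(nchar(genomic)))[seq_along(genomic)]
  is_exon_genomic <- if (strand == "+") rep(c(TRUE, FALSE), length.out =
    2L * n - 1L) else rev(rep(c(TRUE, FALSE), length.out = 2L * n - 1L))
  tx_idx_genomic <- if (strand == "+") (seq_len(2L * n - 1L) + 1L) %/% 2L else
    rev((seq_len(2L * n - 1L) + 1L) %/% 2L)
  starts <- ends <- integer(n)
  for (k in seq_len(2L * n - 1L)) {
    if (is_exon_genomic[k]) {
      i <- tx_idx_genomic[k]
      starts[i] <- offs[k] + 1L
      ends[i] <- offs[k] + nchar(genomic[k])
    }
  }
  exon_ids <- sprintf("%s.e%d", gene_id, seq_len(n))
  exons <- data.frame(exon_id = exon_ids, chrom = chrom, start = starts,
                      end = ends, strand = strand, frame_offset = phases,
                      stringsAsFactors = FALSE)
  if (is.null(transcripts)) transcripts <- list(t1 = exon_ids)
  gene <- gene_model(gene_id, symbol = toupper(gene_id), chrom = chrom,
                     strand = strand, exons = exons,
                     transcripts = transcripts,
                     protein_ids = paste0("P_", gene_id))
  list(assembly = genome_assembly(stats::setNames(chrom_seq, chrom)),
       gene = gene, exons = gene$exons,
       adjacency = build_exon_comb_kb(list(gene)))
}

# naive substring-scan oracle for peptide->protein mapping
naive_map <- function(peptides, proteins) {
  rows <- list()
  for (i in seq_len(nrow(peptides))) {
    pat <- toupper(peptides$sequence[i])
    for (p in names(proteins)) {
      txt <- toupper(proteins[[p]])
      start <- 1L
      repeat {
        hit <- regexpr(pat, substring(txt, start), fixed = TRUE)
        if (hit == -1L) break
        off <- start + as.integer(hit) - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          peptide_id = peptides$peptide_id[i], protein_id = p,
          offset = off, stringsAsFactors = FALSE)
        start <- off + 1L
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide_id = character(0), protein_id = character(0),
               offset = integer(0))
  out[order(out$protein_id, out$offset, out$peptide_id), , drop = FALSE]
}

# canonical comparison keys for oracle/pipeline equivalence
region_keys <- function(rt) {
  sort(paste(rt$region_type, rt$loc, rt$orf,
             if ("peptide" %in% names(rt)) rt$peptide else rt$wild_peptide))
}

# mirror a fixture: reverse-complement every chromosome and flip all
# coordinates and strands; the peptide multiset must be invariant
mirror_fixture <- function(fx) {
  asm <- vapply(unclass(fx$assembly), function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    "")
  lens <- nchar(fx$assembly)
  genes <- lapply(fx$genes, function(g) {
    L <- lens[[g$chrom]]
    ex <- g$exons
    new_start <- L - ex$end + 1L
    new_end <- L - ex$start + 1L
    ex$start <- new_start
    ex$end <- new_end
    ex$strand <- ifelse(ex$strand == "+", "-", "+")
    gene_model(g$gene_id, g$symbol, g$chrom,
               ifelse(g$strand == "+", "-", "+"), ex, g$transcripts,
               g$protein_ids)
  })
  list(assembly = genome_assembly(asm), genes = genes)
}
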