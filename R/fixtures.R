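# Seeded synthetic genome/annotation/SNP fixtures with ground truth.
# Every downstream module is testable against these with no external
# download. SNP consequences are computed at plant time by local codon
# translation, independently of the region-generation code under test.

.SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                    c("T", "C", "A", "G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

.rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

.classify_codon <- function(ref_codon, alt_codon) {
  code <- Biostrings::GENETIC_CODE
  aa_ref <- unname(code[ref_codon])
  aa_alt <- unname(code[alt_codon])
  cls <- if (aa_alt == "*") "stop" else
    if (aa_alt == aa_ref) "synonymous" else "nonsynonymous"
  list(class = cls, aa_ref = aa_ref, aa_alt = aa_alt)
}

#' Generate a synthetic genome fixture with ground truth
#'
#' Builds `n_genes` single- (or, with `cassette`, two-) transcript genes
#' with valid CDS phase chaining, random intron/flank sequence, planted
#' SNPs of known consequence, and writes standard-format FASTA, GFF3,
#' VCF and protein FASTA files plus a JSON ground-truth record.
#'
#' Defaults describe a compact but structurally realistic eukaryotic
#' locus: 3-5 coding exons of 30-120 nt, introns of 20-60 nt, a mix of
#' strands, and a stop-free annotated frame so that every annotated
#' region survives validation.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range `c(min, max)`.
#' @param exon_len,intron_len Length ranges in nucleotides.
#' @param strands Strand pool sampled per gene.
#' @param stop_free Draw coding sequence from sense codons only, so the
#'   annotated frame is stop-free.
#' @param snps_per_gene Number of SNPs to plant per gene (classes cycled
#'   through synonymous / non-synonymous / stop-introducing).
#' @param cassette Add a second annotated transcript per eligible gene
#'   that skips one middle exon (forces exon lengths to multiples of 3
#'   so frames stay consistent).
#' @param seed Integer RNG seed (required; same seed, same files).
#' @param out_dir Output directory; `NULL` skips file writing.
#' @return List with `assembly`, `genes` (list of [gene_model()]),
#'   `snps` (`data.frame`), `proteins` (named character vector of
#'   annotated translations per transcript), `truth`, `paths`.
#' @export
make_genome <- function(n_genes = 3L, exons_per_gene = c(3L, 5L),
                        exon_len = c(30L, 120L), intron_len = c(20L, 60L),
                        strands = c("+", "-"), stop_free = TRUE,
                        snps_per_gene = 3L, cassette = FALSE, seed,
                        out_dir = NULL) {
  stopifnot(!missing(seed), exon_len[1] >= 3L, intron_len[1] >= 1L,
            exons_per_gene[1] >= 1L)
  withr::with_seed(seed, {
    assembly <- character(0)
    genes <- list()
    snp_rows <- list()
    truth_genes <- list()
    proteins <- character(0)
    snp_serial <- 0L
    for (gi in seq_len(n_genes)) {
      gid <- sprintf("gene%02d", gi)
      chrom <- sprintf("chr%02d", gi)
      strand <- sample(strands, 1L)
      n_ex <- if (exons_per_gene[1] == exons_per_gene[2]) exons_per_gene[1]
        else sample(seq(exons_per_gene[1], exons_per_gene[2]), 1L)
      lens <- sample(seq(exon_len[1], exon_len[2]), n_ex, replace = TRUE)
      cass_idx <- NA_integer_
      if (cassette && n_ex >= 3L) {
        cass_idx <- (n_ex + 1L) %/% 2L
        lens <- lens + (3L - lens %% 3L) %% 3L  # phase 0 everywhere
      } else {
        total <- sum(lens)
        lens[n_ex] <- lens[n_ex] + (3L - total %% 3L) %% 3L
      }
      total <- sum(lens)
      cds <- if (stop_free)
        paste(sample(.SENSE_CODONS, total %/% 3L, replace = TRUE),
              collapse = "")
      else .rand_bases(total)
      cum <- c(0L, cumsum(lens))
      exon_seq <- substring(cds, cum[-length(cum)] + 1L, cum[-1L])
      phase <- (3L - cum[seq_len(n_ex)] %% 3L) %% 3L
      introns <- vapply(seq_len(max(n_ex - 1L, 0L)), function(i)
        .rand_bases(sample(seq(intron_len[1], intron_len[2]), 1L)), "")
      # layout: transcription order pieces; genomic order depends on strand
      piece_seq <- character(2L * n_ex - 1L)
      piece_is_exon <- logical(2L * n_ex - 1L)
      piece_tx <- integer(2L * n_ex - 1L)
      for (i in seq_len(n_ex)) {
        piece_seq[2L * i - 1L] <- exon_seq[i]
        piece_is_exon[2L * i - 1L] <- TRUE
        piece_tx[2L * i - 1L] <- i
        if (i < n_ex) piece_seq[2L * i] <- introns[i]
      }
      genomic_order <- if (strand == "+") seq_along(piece_seq)
        else rev(seq_along(piece_seq))
      flank5 <- .rand_bases(60L)
      flank3 <- .rand_bases(60L)
      chrom_seq <- flank5
      ex_start <- integer(n_ex)
      ex_end <- integer(n_ex)
      pos <- nchar(flank5)
      for (k in genomic_order) {
        s <- piece_seq[k]
        if (strand == "-") s <- revcomp(s)
        if (piece_is_exon[k]) {
          ex_start[piece_tx[k]] <- pos + 1L
          ex_end[piece_tx[k]] <- pos + nchar(s)
        }
        chrom_seq <- paste0(chrom_seq, s)
        pos <- pos + nchar(s)
      }
      chrom_seq <- paste0(chrom_seq, flank3)
      assembly[chrom] <- chrom_seq
      exon_ids <- sprintf("%s.e%d", gid, seq_len(n_ex))
      exons <- data.frame(exon_id = exon_ids, chrom = chrom,
                          start = ex_start, end = ex_end, strand = strand,
                          frame_offset = phase, stringsAsFactors = FALSE)
      transcripts <- list(t1 = exon_ids)
      if (!is.na(cass_idx)) transcripts$t2 <- exon_ids[-cass_idx]
      names(transcripts) <- paste0(gid, ".", names(transcripts))
      prot_ids <- paste0("P_", names(transcripts))
      genes[[gid]] <- gene_model(gid, symbol = toupper(gid), chrom = chrom,
                                 strand = strand, exons = exons,
                                 transcripts = transcripts,
                                 protein_ids = prot_ids)
      # annotated translations (frame 0 of the spliced CDS)
      for (ti in seq_along(transcripts)) {
        tx_cds <- paste(exon_seq[match(transcripts[[ti]], exon_ids)],
                        collapse = "")
        aa <- paste(Biostrings::GENETIC_CODE[
          substring(tx_cds, seq(1L, nchar(tx_cds) - 2L, 3L),
                    seq(3L, nchar(tx_cds), 3L))], collapse = "")
        proteins[prot_ids[ti]] <- aa
      }
      # plant SNPs with known consequence (codon fully inside one exon,
      # never the exon's last complete codon)
      want <- rep(c("synonymous", "nonsynonymous", "stop"),
                  length.out = snps_per_gene)
      used_pos <- integer(0)
      for (cls in want) {
        planted <- FALSE
        for (try in seq_len(300L)) {
          e <- sample(n_ex, 1L)
          ncod <- (lens[e] - phase[e]) %/% 3L
          if (ncod < 2L) next
          cidx <- sample(ncod - 1L, 1L)
          w <- sample(3L, 1L)
          q <- phase[e] + 3L * (cidx - 1L) + w    # 1-based coding pos in exon
          gpos <- if (strand == "+") ex_start[e] + q - 1L else ex_end[e] - q + 1L
          if (gpos %in% used_pos) next
          ref_codon <- substr(exon_seq[e], phase[e] + 3L * (cidx - 1L) + 1L,
                              phase[e] + 3L * cidx)
          ref_base <- substr(ref_codon, w, w)
          hits <- character(0)
          for (alt in setdiff(c("A", "C", "G", "T"), ref_base)) {
            alt_codon <- ref_codon
            substr(alt_codon, w, w) <- alt
            if (.classify_codon(ref_codon, alt_codon)$class == cls)
              hits <- c(hits, alt)
          }
          if (!length(hits)) next
          alt <- hits[1L]
          alt_codon <- ref_codon
          substr(alt_codon, w, w) <- alt
          info <- .classify_codon(ref_codon, alt_codon)
          snp_serial <- snp_serial + 1L
          ref_fwd <- if (strand == "+") ref_base else .complement(ref_base)
          alt_fwd <- if (strand == "+") alt else .complement(alt)
          snp_rows[[length(snp_rows) + 1L]] <- data.frame(
            snp_id = sprintf("rs%04d", snp_serial), chrom = chrom,
            pos = gpos, ref = ref_fwd, alt = alt_fwd, class = cls,
            gene_id = gid, exon_id = exon_ids[e],
            aa_ref = info$aa_ref, aa_alt = info$aa_alt,
            stringsAsFactors = FALSE)
          used_pos <- c(used_pos, gpos)
          planted <- TRUE
          break
        }
        if (!planted)
          message("make_genome: could not plant a ", cls, " SNP in ", gid)
      }
      n_adj <- (n_ex - 1L) + (if (!is.na(cass_idx)) 1L else 0L)
      truth_genes[[gid]] <- list(
        n_exons = n_ex, strand = strand, cassette_exon =
          if (is.na(cass_idx)) NULL else exon_ids[cass_idx],
        candidate_counts = list(
          EXON_KB = n_ex, E_E_KB = n_adj,
          E_I_TH = 3L * max(n_ex - 1L, 0L),
          I_E_TH = 3L * max(n_ex - 1L, 0L),
          E_E_TH = 3L * (choose(n_ex, 2L) - n_adj)))
    }
    snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
      data.frame(snp_id = character(0), chrom = character(0),
                 pos = integer(0), ref = character(0), alt = character(0),
                 class = character(0), gene_id = character(0),
                 exon_id = character(0), aa_ref = character(0),
                 aa_alt = character(0))
    rownames(snps) <- NULL
    truth <- list(seed = seed,
                  config = list(n_genes = n_genes,
                                exons_per_gene = exons_per_gene,
                                exon_len = exon_len,
                                intron_len = intron_len,
                                stop_free = stop_free,
                                cassette = cassette),
                  genes = truth_genes,
                  snps = snps)
    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        genome = file.path(out_dir, "genome.fasta"),
        gff = file.path(out_dir, "annotation.gff3"),
        vcf = file.path(out_dir, "snps.vcf"),
        proteins = file.path(out_dir, "proteins.fasta"),
        truth = file.path(out_dir, "truth.json"))
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(assembly),
                                  paths$genome, width = 70L)
      write_gff3(genes, paths$gff)
      write_vcf(snps, paths$vcf, assembly)
      Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins),
                                  paths$proteins, width = 60L)
      jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    list(assembly = genome_assembly(assembly), genes = genes, snps = snps,
         proteins = proteins, truth = truth, paths = paths)
  })
}

#' Write gene models as GFF3 (CDS features)
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    for (tid in names(g$transcripts)) {
      for (eid in g$transcripts[[tid]]) {
        ex <- g$exons[g$exons$exon_id == eid, ]
        pid <- if (length(g$protein_ids))
          paste0("P_", tid) else NA_character_
        attrs <- sprintf(
          "ID=cds:%s:%s;gene_id=%s;transcript_id=%s;exon_id=%s;gene_name=%s%s",
          tid, eid, g$gene_id, tid, eid, g$symbol,
          if (is.na(pid)) "" else paste0(";protein_id=", pid))
        lines <- c(lines, paste(ex$chrom, "synthetic", "CDS", ex$start,
                                ex$end, ".", ex$strand, ex$frame_offset,
                                attrs, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write SNPs as a minimal VCF 4.2 file
#'
#' Records at the same position are merged into one multi-allelic line.
#'
#' @param snps SNP `data.frame` (columns snp_id, chrom, pos, ref, alt).
#' @param path Output path.
#' @param assembly Optional assembly for contig header lines.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(snps, path, assembly = NULL) {
  hdr <- c("##fileformat=VCFv4.2")
  if (!is.null(assembly))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(assembly),
                          nchar(assembly)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  recs <- character(0)
  if (nrow(snps)) {
    key <- paste(snps$chrom, snps$pos)
    for (k in unique(key)) {
      s <- snps[key == k, , drop = FALSE]
      recs <- c(recs, paste(s$chrom[1], s$pos[1], s$snp_id[1], s$ref[1],
                            paste(unique(s$alt), collapse = ","), ".", ".",
                            ".", sep = "\t"))
    }
    ord <- order(vapply(strsplit(recs, "\t"), `[[`, "", 1L),
                 as.integer(vapply(strsplit(recs, "\t"), `[[`, "", 2L)))
    recs <- recs[ord]
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
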