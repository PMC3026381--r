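#' @useDynLib splicepep, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

# ---- coordinate conventions -------------------------------------------------
# All genomic coordinates in this package are 1-based and inclusive on both
# ends (Ensembl/GFF3/VCF convention). Any half-open arithmetic is internal.

VALID_STRANDS <- c("+", "-")

# standard genetic code, indexed by codon (from Biostrings)
.CODON_TABLE <- Biostrings::GENETIC_CODE

#' Read a genome assembly from a FASTA file
#'
#' Loads chromosome sequences into a named character vector, uppercased.
#' The chromosome name is the first whitespace-delimited token of each
#' FASTA header. Gzip-compressed files are read transparently.
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A named character vector of class `genome_assembly` mapping
#'   chromosome name to uppercase nucleotide sequence.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nm <- vapply(strsplit(names(seqs), "[ \t]"), `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  out <- toupper(as.character(seqs))
  names(out) <- nm
  structure(out, class = "genome_assembly")
}

#' Construct a genome assembly from in-memory sequences
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @return A `genome_assembly` object.
#' @export
genome_assembly <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(seqs)))
  if (anyDuplicated(names(seqs))) stop("duplicate chromosome name")
  structure(toupper(seqs), class = "genome_assembly")
}

#' Reverse-complement nucleotide strings
#'
#' Plain-character implementation: region generation calls this once per
#' candidate segment, where heavyweight sequence containers would
#' dominate the runtime.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(chartr("ACGTNacgtn", "TGCANtgcan", x), function(s)
    intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

#' Extract an oriented genomic subsequence
#'
#' Returns the forward-strand substring for `+`, its reverse complement
#' for `-`. Coordinates are 1-based inclusive.
#'
#' @param assembly A `genome_assembly`.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return Nucleotide string of length `end - start + 1`.
#' @export
extract_oriented <- function(assembly, chrom, start, end, strand) {
  if (!chrom %in% names(assembly)) stop("unknown chromosome: ", chrom)
  if (!strand %in% VALID_STRANDS) stop("invalid strand: ", strand)
  len <- nchar(assembly[[chrom]])
  if (start < 1L || start > end || end > len) {
    stop(sprintf("out-of-bounds interval %s:%d-%d (chromosome length %d)",
                 chrom, start, end, len))
  }
  s <- substr(assembly[[chrom]], start, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Translate a cDNA string
#'
#' Skips `offset` bases, translates successive complete codons with the
#' standard genetic code and drops any incomplete 3' tail. Stop codons
#' become `*`; any codon containing an ambiguous base becomes `X`.
#'
#' @param cdna Nucleotide string.
#' @param offset Integer in 0..2, number of 5' bases to skip.
#' @return Amino-acid string (possibly empty).
#' @export
translate_cdna <- function(cdna, offset = 0L) {
  if (!nzchar(cdna)) stop("empty cDNA")
  if (!offset %in% 0:2) stop("offset must be 0, 1 or 2")
  n <- nchar(cdna) - offset
  if (n < 3L) return("")
  starts <- seq.int(offset + 1L, offset + 3L * (n %/% 3L), by = 3L)
  aa <- .CODON_TABLE[substring(cdna, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"   # any codon containing an ambiguous base
  paste(aa, collapse = "")
}

# ---- gene models ------------------------------------------------------------

#' Construct a gene model
#'
#' A gene model holds the coding (CDS) exon structure of one gene. "Exon"
#' throughout this package means the coding part of an exon; UTRs are
#' excluded at read time. Exons are stored in transcription order (5' to
#' 3'), i.e. ascending genomic coordinates on `+` genes and descending on
#' `-` genes.
#'
#' @param gene_id Gene identifier.
#' @param symbol Gene symbol (or `NA`).
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `exon_id`, `chrom`, `start`,
#'   `end`, `strand`, `frame_offset` (GFF3 phase semantics: bases of the
#'   exon's coding sequence to skip so translation starts on a codon
#'   boundary).
#' @param transcripts Named list mapping transcript id to an ordered
#'   character vector of exon ids (transcription order).
#' @param protein_ids Character vector of mapped protein ids (may be
#'   empty).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, symbol = NA_character_, chrom, strand,
                       exons, transcripts = list(), protein_ids = character(0)) {
  stopifnot(strand %in% VALID_STRANDS,
            all(c("exon_id", "chrom", "start", "end", "strand",
                  "frame_offset") %in% names(exons)))
  if (any(exons$start > exons$end)) stop("exon with start > end")
  if (!all(exons$frame_offset %in% 0:2)) stop("frame_offset must be 0, 1 or 2")
  ord <- if (strand == "+") order(exons$start, exons$end)
         else order(-exons$end, -exons$start)
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL
  for (tid in names(transcripts)) {
    if (!all(transcripts[[tid]] %in% exons$exon_id))
      stop("transcript ", tid, " references unknown exon")
  }
  structure(list(gene_id = gene_id, symbol = symbol, chrom = chrom,
                 strand = strand, exons = exons, transcripts = transcripts,
                 protein_ids = unique(protein_ids)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d(%s)  %d CDS exon(s), %d transcript(s)\n",
              x$gene_id, x$symbol, x$chrom, min(x$exons$start),
              max(x$exons$end), x$strand, nrow(x$exons),
              length(x$transcripts)))
  invisible(x)
}

#' Read CDS-level gene models from a GFF3 file
#'
#' Only `CDS` features are used. Each CDS line must carry `gene_id` and
#' `transcript_id` attributes and a phase column; optional attributes
#' `exon_id`, `gene_name` and `protein_id` are honoured. Identical CDS
#' intervals shared by several transcripts of a gene are deduplicated
#' into a single coding exon with a stable id.
#'
#' @param path Path to a (possibly gzipped) GFF3 file.
#' @param assembly Optional `genome_assembly`; when given, CDS features on
#'   chromosomes absent from the assembly raise an error.
#' @return Named list of [gene_model()] objects, sorted by gene id.
#' @export
read_annotation <- function(path, assembly = NULL) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", path)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = if ("phase" %in% names(S4Vectors::mcols(gr)))
      as.integer(gr$phase) else NA_integer_,
    stringsAsFactors = FALSE)
  for (key in c("gene_id", "transcript_id", "exon_id", "gene_name",
                "protein_id")) {
    df[[key]] <- if (key %in% names(S4Vectors::mcols(gr)))
      as.character(S4Vectors::mcols(gr)[[key]]) else NA_character_
  }
  if (anyNA(df$phase)) stop("CDS feature without frame/phase in ", path)
  if (anyNA(df$gene_id) || anyNA(df$transcript_id))
    stop("CDS feature without gene_id/transcript_id attribute in ", path)
  if (!all(df$strand %in% VALID_STRANDS)) stop("CDS feature without strand")
  if (!is.null(assembly)) {
    bad <- setdiff(unique(df$chrom), names(assembly))
    if (length(bad)) stop("CDS on unknown chromosome: ",
                          paste(bad, collapse = ", "))
  }
  genes <- list()
  for (gid in sort(unique(df$gene_id))) {
    g <- df[df$gene_id == gid, , drop = FALSE]
    strand <- unique(g$strand)
    chrom <- unique(g$chrom)
    if (length(strand) != 1L || length(chrom) != 1L)
      stop("gene ", gid, " spans multiple chromosomes or strands")
    key <- paste(g$chrom, g$start, g$end, sep = ":")
    first <- !duplicated(key)
    ex <- g[first, , drop = FALSE]
    # phase must agree across transcripts sharing a CDS interval
    ph_ok <- tapply(g$phase, key, function(p) length(unique(p)) == 1L)
    if (!all(ph_ok)) stop("gene ", gid, ": inconsistent phase for a shared CDS interval")
    exon_id <- ifelse(is.na(ex$exon_id),
                      paste0(gid, ":", ex$start, "-", ex$end), ex$exon_id)
    exons <- data.frame(exon_id = exon_id, chrom = ex$chrom,
                        start = ex$start, end = ex$end, strand = ex$strand,
                        frame_offset = ex$phase, stringsAsFactors = FALSE)
    id_of <- stats::setNames(exon_id, key[first])
    tx_order <- function(rows) {
      o <- if (strand == "+") order(rows$start) else order(-rows$end)
      unname(id_of[paste(rows$chrom, rows$start, rows$end, sep = ":")[o]])
    }
    transcripts <- lapply(split(g, g$transcript_id), tx_order)
    symbol <- stats::na.omit(unique(g$gene_name))
    prot <- stats::na.omit(unique(g$protein_id))
    genes[[gid]] <- gene_model(
      gene_id = gid,
      symbol = if (length(symbol)) symbol[1] else NA_character_,
      chrom = chrom, strand = strand, exons = exons,
      transcripts = transcripts[order(names(transcripts))],
      protein_ids = as.character(prot))
  }
  genes
}

#' Read single-nucleotide substitutions from a VCF file
#'
#' Keeps only records with a 1-base REF and 1-base ALT allele;
#' multi-allelic records are expanded to one row per alternate allele
#' under the same variant id. Indels and multi-nucleotide variants are
#' skipped and counted.
#'
#' @param path Path to a (possibly gzipped) VCF 4.x file.
#' @return `data.frame` with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt` (forward-strand alleles); attribute `n_skipped` carries the
#'   number of non-SNV records dropped.
#' @export
read_snps <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  ids <- names(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  rows <- list()
  n_skipped <- 0L
  for (i in seq_along(rr)) {
    a <- as.character(alts[[i]])
    ok <- nchar(ref[i]) == 1L & nchar(a) == 1L &
      ref[i] %in% c("A", "C", "G", "T") & a %in% c("A", "C", "G", "T")
    n_skipped <- n_skipped + sum(!ok)
    if (any(ok)) {
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = ids[i], chrom = chrom[i], pos = pos[i], ref = ref[i],
        alt = a[ok], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0))
  rownames(out) <- NULL
  if (n_skipped > 0L)
    message("read_snps: skipped ", n_skipped, " non-SNV allele(s)")
  attr(out, "n_skipped") <- n_skipped
  out
}
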