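# Peptide region generation: the five region types and their validation
# protocols.
#
#   EXON_KB  whole coding exon, annotated frame, stop not tolerated
#   E_E_KB   annotated exon-exon junction, <=120 nt flanks, annotated
#            frame of the 5' exon, stop not tolerated
#   E_I_TH   exon + adjacent downstream intron, all 3 frames, stop
#            tolerated in the 3' (intron) segment (truncates)
#   I_E_TH   adjacent upstream intron + exon, all 3 frames, stop not
#            tolerated
#   E_E_TH   unannotated within-gene exon pair, all 3 frames, stop in the
#            5' exon fatal, stop in the 3' exon truncates
#
# A junction region's cDNA is at most 240 nt (120 nt per flank), sized so
# that the longest MS-observable peptide (80 aa = 240 nt) crossing the
# splice site is always contained.

REGION_TYPES <- c("EXON_KB", "E_E_KB", "E_I_TH", "I_E_TH", "E_E_TH")

#' Region-generation configuration
#'
#' @param flank_nt Maximum nucleotides taken from each side of a splice
#'   site (default 120, i.e. a 240-nt window = 80 aa).
#' @param min_peptide_len Minimum retained peptide length in residues
#'   (default 1 = keep all).
#' @param enabled_region_types Character vector of region types to
#'   generate.
#' @return A `region_config` list.
#' @export
region_config <- function(flank_nt = 120L, min_peptide_len = 1L,
                          enabled_region_types = REGION_TYPES) {
  stopifnot(flank_nt >= 3L, min_peptide_len >= 1L,
            all(enabled_region_types %in% REGION_TYPES))
  structure(list(flank_nt = as.integer(flank_nt),
                 min_peptide_len = as.integer(min_peptide_len),
                 enabled_region_types = enabled_region_types),
            class = "region_config")
}

#' Frame offset of a trimmed coding segment
#'
#' When a segment starts `trim` bases into an exon's coding sequence, the
#' number of bases to skip so that translation realigns with the exon's
#' annotated codon boundaries is `(exon_frame - trim) mod 3`.
#'
#' @param exon_frame Annotated frame offset of the exon (0, 1 or 2).
#' @param trim Non-negative number of bases trimmed from the segment 5'
#'   end.
#' @return Frame offset (0, 1 or 2) for the trimmed segment.
#' @export
segment_frame_offset <- function(exon_frame, trim) {
  stopifnot(exon_frame %in% 0:2, trim >= 0L)
  as.integer((exon_frame - trim) %% 3L)
}

# oriented flank intervals ----------------------------------------------------
# "last k" = the k bases at the segment's 3' end in transcription
# orientation; "first k" = the k bases at its 5' end.
.flank_last <- function(start, end, strand, k) {
  taken <- min(k, end - start + 1L)
  if (strand == "+") c(end - taken + 1L, end) else c(start, start + taken - 1L)
}
.flank_first <- function(start, end, strand, k) {
  taken <- min(k, end - start + 1L)
  if (strand == "+") c(start, start + taken - 1L) else c(end - taken + 1L, end)
}

# ---- peptide estimation protocol -------------------------------------------
# Shared by wild-type region generation and SNP variant application.
# junction_offset: 0-based index into cdna of the first base of the 3'
# segment, or NA for EXON_KB.
#
# Returns list(ok, peptide, reason, truncated).
estimate_peptide <- function(cdna, orf, region_type, junction_offset = NA,
                             min_peptide_len = 1L) {
  nb <- nchar(cdna)
  if (orf >= nb) return(list(ok = FALSE, reason = "too_short"))
  pep <- translate_cdna(cdna, orf)
  if (!nzchar(pep)) return(list(ok = FALSE, reason = "too_short"))
  stops <- which(strsplit(pep, "")[[1]] == "*")
  truncated <- FALSE
  tolerant <- region_type %in% c("E_I_TH", "E_E_TH")
  if (length(stops)) {
    if (tolerant) {
      k <- stops[1L]
      codon_end0 <- orf + 3L * k - 1L      # 0-based index of codon's last base
      if (codon_end0 < junction_offset)    # codon wholly in the 5' segment
        return(list(ok = FALSE, reason = "stop_in_5prime"))
      pep <- substr(pep, 1L, k - 1L)
      truncated <- TRUE
    } else {
      if (length(stops) == 1L && stops == nchar(pep)) {
        pep <- substr(pep, 1L, nchar(pep) - 1L)  # natural C-terminus
      } else {
        return(list(ok = FALSE, reason = "internal_stop"))
      }
    }
  }
  if (grepl("X", pep, fixed = TRUE))
    return(list(ok = FALSE, reason = "ambiguous"))
  if (nchar(pep) < min_peptide_len)
    return(list(ok = FALSE, reason = "too_short"))
  if (!is.na(junction_offset)) {
    span_start0 <- orf
    span_end0 <- orf + 3L * nchar(pep) - 1L
    if (!(span_start0 < junction_offset && span_end0 >= junction_offset))
      return(list(ok = FALSE, reason = "junction_not_covered"))
  }
  list(ok = TRUE, peptide = pep, reason = NA_character_, truncated = truncated)
}

# ---- region construction ----------------------------------------------------

.new_region <- function(gene_id, region_type, segments, orf, cdna, peptide,
                        junction_offset, source_exons) {
  structure(list(region_id = NA_character_, gene_id = gene_id,
                 region_type = region_type, segments = segments, orf = orf,
                 cdna = cdna, wild_peptide = peptide,
                 junction_offset = junction_offset,
                 source_exons = source_exons),
            class = "peptide_region")
}

#' @export
print.peptide_region <- function(x, ...) {
  loc <- paste(sprintf("%s:%d-%d", x$segments$chrom, x$segments$start,
                       x$segments$end), collapse = "|")
  cat(sprintf("<peptide_region> %s %s %s orf=%d %s(%s) peptide=%s\n",
              ifelse(is.na(x$region_id), "(unassigned)", x$region_id),
              x$region_type, x$gene_id, x$orf, loc, x$segments$strand[1],
              x$wild_peptide))
  invisible(x)
}

.segments_df <- function(chrom, starts, ends, strand, roles) {
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(ends), strand = strand, role = roles,
             stringsAsFactors = FALSE)
}

# Build one candidate (segments already in transcription order) and apply
# the estimation protocol for each requested orf. Returns list of regions
# and a data.frame of rejections.
.candidates_from_segments <- function(gene, region_type, segments, orfs,
                                      assembly, source_exons, config) {
  seqs <- mapply(extract_oriented,
                 chrom = segments$chrom, start = segments$start,
                 end = segments$end, strand = segments$strand,
                 MoreArgs = list(assembly = assembly), USE.NAMES = FALSE)
  cdna <- paste(seqs, collapse = "")
  junction_offset <- if (nrow(segments) > 1L) nchar(seqs[1L]) else NA
  regions <- list()
  rej <- list()
  desc <- paste(source_exons, collapse = "|")
  for (orf in orfs) {
    est <- estimate_peptide(cdna, orf, region_type, junction_offset,
                            config$min_peptide_len)
    if (est$ok) {
      regions[[length(regions) + 1L]] <-
        .new_region(gene$gene_id, region_type, segments, orf, cdna,
                    est$peptide, junction_offset, source_exons)
    } else {
      rej[[length(rej) + 1L]] <- data.frame(
        gene_id = gene$gene_id, region_type = region_type,
        candidate = desc, orf = orf, reason = est$reason,
        stringsAsFactors = FALSE)
    }
  }
  list(regions = regions,
       rejections = if (length(rej)) do.call(rbind, rej) else NULL)
}

#' Generate the exonic region of one coding exon
#'
#' Full-length exon cDNA translated in the annotated frame. A stop codon
#' as the final residue is stripped (natural C-terminus); any internal
#' stop invalidates the region.
#'
#' @param exon One-row exon `data.frame` (see [build_exon_kb()]).
#' @param gene The owning [gene_model()].
#' @param assembly A `genome_assembly`.
#' @param config A [region_config()].
#' @return List with elements `regions` (0 or 1 `peptide_region`) and
#'   `rejections` (`NULL` or a one-row data.frame).
#' @export
gen_exon_region <- function(exon, gene, assembly, config = region_config()) {
  segments <- .segments_df(exon$chrom, exon$start, exon$end, exon$strand,
                           "exon")
  .candidates_from_segments(gene, "EXON_KB", segments, exon$frame_offset,
                            assembly, exon$exon_id, config)
}

# shared E-E builder (KB and TH differ only in orfs and type)
.ee_candidate <- function(gene, ex5, ex3, region_type, assembly, config) {
  k <- config$flank_nt
  iv5 <- .flank_last(ex5$start, ex5$end, ex5$strand, k)
  iv3 <- .flank_first(ex3$start, ex3$end, ex3$strand, k)
  segments <- .segments_df(c(ex5$chrom, ex3$chrom), c(iv5[1], iv3[1]),
                           c(iv5[2], iv3[2]), c(ex5$strand, ex3$strand),
                           c("exon5", "exon3"))
  if (region_type == "E_E_KB") {
    trim <- (ex5$end - ex5$start + 1L) - (iv5[2] - iv5[1] + 1L)
    orfs <- segment_frame_offset(ex5$frame_offset, trim)
  } else {
    orfs <- 0:2
  }
  .candidates_from_segments(gene, region_type, segments, orfs, assembly,
                            c(ex5$exon_id, ex3$exon_id), config)
}

#' Generate an annotated exon-exon junction region
#'
#' cDNA is the last `flank_nt` bases of the 5' exon joined to the first
#' `flank_nt` bases of the 3' exon, translated in the frame propagated
#' from the 5' exon's annotation; stops are not tolerated except as the
#' final residue, and the surviving peptide must cross the junction.
#'
#' @param ex5,ex3 One-row exon data.frames, 5' and 3' members of an
#'   annotated adjacency.
#' @inheritParams gen_exon_region
#' @return List with `regions` and `rejections`.
#' @export
gen_eekb_region <- function(ex5, ex3, gene, assembly,
                            config = region_config()) {
  .ee_candidate(gene, ex5, ex3, "E_E_KB", assembly, config)
}

# intron between consecutive gene-level exons (transcription order).
# Returns c(start, end) genomic interval or NULL when the exons abut or
# overlap.
.intron_between <- function(up, down, strand) {
  if (strand == "+") iv <- c(up$end + 1L, down$start - 1L)
  else iv <- c(down$end + 1L, up$start - 1L)
  if (iv[1] > iv[2]) NULL else iv
}

#' Generate hypothetical exon-intron junction regions
#'
#' Exon 3' flank joined to the first bases of the adjacent downstream
#' intron, translated in all three frames. A stop codon whose codon lies
#' wholly in the exon segment rejects that frame; a stop reaching into
#' the intron truncates the peptide, which is kept only if it still
#' crosses the junction.
#'
#' @param exon One-row exon `data.frame`.
#' @param intron `c(start, end)` genomic interval of the downstream
#'   intron.
#' @inheritParams gen_exon_region
#' @return List with `regions` (0-3) and `rejections`.
#' @export
gen_eith_regions <- function(exon, intron, gene, assembly,
                             config = region_config()) {
  k <- config$flank_nt
  iv5 <- .flank_last(exon$start, exon$end, exon$strand, k)
  iv3 <- .flank_first(intron[1], intron[2], exon$strand, k)
  segments <- .segments_df(exon$chrom, c(iv5[1], iv3[1]), c(iv5[2], iv3[2]),
                           exon$strand, c("exon5", "intron3"))
  .candidates_from_segments(gene, "E_I_TH", segments, 0:2, assembly,
                            c(exon$exon_id, "intron"), config)
}

#' Generate hypothetical intron-exon junction regions
#'
#' Last bases of the adjacent upstream intron joined to the exon 5'
#' flank, all three frames; stops are not tolerated anywhere except the
#' final residue.
#'
#' @param intron `c(start, end)` genomic interval of the upstream intron.
#' @param exon One-row exon `data.frame`.
#' @inheritParams gen_exon_region
#' @return List with `regions` (0-3) and `rejections`.
#' @export
gen_ieth_regions <- function(intron, exon, gene, assembly,
                             config = region_config()) {
  k <- config$flank_nt
  iv5 <- .flank_last(intron[1], intron[2], exon$strand, k)
  iv3 <- .flank_first(exon$start, exon$end, exon$strand, k)
  segments <- .segments_df(exon$chrom, c(iv5[1], iv3[1]), c(iv5[2], iv3[2]),
                           exon$strand, c("intron5", "exon3"))
  .candidates_from_segments(gene, "I_E_TH", segments, 0:2, assembly,
                            c("intron", exon$exon_id), config)
}

#' Generate hypothetical exon-exon junction regions of one gene
#'
#' Candidate pairs are ordered within-gene exon pairs (5' member strictly
#' upstream in transcription order) whose genomic intervals do not
#' overlap and that are absent from the annotated adjacency
#' knowledgebase. Each pair is translated in all three frames; a stop in
#' the 5' exon segment rejects the frame, a stop reaching the 3' exon
#' segment truncates.
#'
#' @param gene A [gene_model()] with at least two exons.
#' @param adjacency Adjacency knowledgebase from [build_exon_comb_kb()].
#' @inheritParams gen_exon_region
#' @return List with `regions` and `rejections`.
#' @export
gen_eeth_regions <- function(gene, adjacency, assembly,
                             config = region_config()) {
  ex <- gene$exons
  n <- nrow(ex)
  regions <- list()
  rejections <- list()
  adj_keys <- paste(adjacency$gene_id, adjacency$exon5, adjacency$exon3)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        a <- ex[i, ]; b <- ex[j, ]
        if (a$start <= b$end && b$start <= a$end) next  # overlapping variants
        if (paste(gene$gene_id, a$exon_id, b$exon_id) %in% adj_keys) next
        res <- .ee_candidate(gene, a, b, "E_E_TH", assembly, config)
        regions <- c(regions, res$regions)
        if (!is.null(res$rejections))
          rejections[[length(rejections) + 1L]] <- res$rejections
      }
    }
  }
  list(regions = regions,
       rejections = if (length(rejections)) do.call(rbind, rejections) else NULL)
}

# ---- full enumeration -------------------------------------------------------

#' Generate all peptide regions of a gene set
#'
#' Runs the five region generators over every gene, orders the output
#' deterministically (gene, region type, genomic start of the 5'
#' segment, genomic start of the 3' segment, frame) and assigns serial
#' region ids `REG000000001, ...`. Every discarded candidate is recorded
#' in the rejection log.
#'
#' @param genes List of coding-filtered [gene_model()] objects.
#' @param adjacency Adjacency knowledgebase from [build_exon_comb_kb()].
#' @param assembly A `genome_assembly`.
#' @param config A [region_config()].
#' @return List with `regions` (list of `peptide_region` with ids) and
#'   `rejections` (`data.frame`: gene_id, region_type, candidate, orf,
#'   reason).
#' @export
generate_all <- function(genes, adjacency, assembly,
                         config = region_config()) {
  all_regions <- list()
  all_rej <- list()
  add <- function(res) {
    all_regions <<- c(all_regions, res$regions)
    if (!is.null(res$rejections))
      all_rej[[length(all_rej) + 1L]] <<- res$rejections
  }
  enabled <- config$enabled_region_types
  gene_ids <- vapply(genes, function(g) g$gene_id, "")
  for (g in genes[order(gene_ids)]) {
    ex <- g$exons
    n <- nrow(ex)
    if ("EXON_KB" %in% enabled) {
      for (i in seq_len(n)) add(gen_exon_region(ex[i, ], g, assembly, config))
    }
    if ("E_E_KB" %in% enabled) {
      adj_g <- adjacency[adjacency$gene_id == g$gene_id, , drop = FALSE]
      for (r in seq_len(nrow(adj_g))) {
        e5 <- ex[ex$exon_id == adj_g$exon5[r], ]
        e3 <- ex[ex$exon_id == adj_g$exon3[r], ]
        if (nrow(e5) == 1L && nrow(e3) == 1L)
          add(gen_eekb_region(e5, e3, g, assembly, config))
      }
    }
    if ("E_I_TH" %in% enabled && n >= 2L) {
      for (i in seq_len(n - 1L)) {
        intron <- .intron_between(ex[i, ], ex[i + 1L, ], g$strand)
        if (!is.null(intron))
          add(gen_eith_regions(ex[i, ], intron, g, assembly, config))
      }
    }
    if ("I_E_TH" %in% enabled && n >= 2L) {
      for (i in seq(2L, n)) {
        intron <- .intron_between(ex[i - 1L, ], ex[i, ], g$strand)
        if (!is.null(intron))
          add(gen_ieth_regions(intron, ex[i, ], g, assembly, config))
      }
    }
    if ("E_E_TH" %in% enabled && n >= 2L)
      add(gen_eeth_regions(g, adjacency, assembly, config))
  }
  # deterministic ordering and serial ids
  if (length(all_regions)) {
    key_gene <- vapply(all_regions, function(r) r$gene_id, "")
    key_type <- match(vapply(all_regions, function(r) r$region_type, ""),
                      REGION_TYPES)
    key_s5 <- vapply(all_regions, function(r) r$segments$start[1L], 0L)
    key_s3 <- vapply(all_regions, function(r)
      if (nrow(r$segments) > 1L) r$segments$start[2L] else 0L, 0L)
    key_orf <- vapply(all_regions, function(r) r$orf, 0L)
    ord <- order(key_gene, key_type, key_s5, key_s3, key_orf)
    all_regions <- all_regions[ord]
    for (i in seq_along(all_regions))
      all_regions[[i]]$region_id <- sprintf("REG%09d", i)
  }
  rejections <- if (length(all_rej)) do.call(rbind, all_rej) else
    data.frame(gene_id = character(0), region_type = character(0),
               candidate = character(0), orf = integer(0),
               reason = character(0))
  rownames(rejections) <- NULL
  list(regions = all_regions, rejections = rejections)
}

#' Tabulate peptide regions
#'
#' @param regions List of `peptide_region` objects.
#' @return `data.frame` with one row per region: id, gene, type, frame,
#'   location of each segment, junction offset, cDNA and peptide.
#' @export
regions_table <- function(regions) {
  if (length(regions) == 0L)
    return(data.frame(region_id = character(0), gene_id = character(0),
                      region_type = character(0), orf = integer(0),
                      chrom = character(0), strand = character(0),
                      loc = character(0), junction_offset = integer(0),
                      cdna = character(0), wild_peptide = character(0)))
  do.call(rbind, lapply(regions, function(r) data.frame(
    region_id = r$region_id, gene_id = r$gene_id,
    region_type = r$region_type, orf = r$orf,
    chrom = r$segments$chrom[1L], strand = r$segments$strand[1L],
    loc = paste(sprintf("%d-%d", r$segments$start, r$segments$end),
                collapse = "|"),
    junction_offset = ifelse(is.na(r$junction_offset), NA_integer_,
                             as.integer(r$junction_offset)),
    cdna = r$cdna, wild_peptide = r$wild_peptide,
    stringsAsFactors = FALSE)))
}
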