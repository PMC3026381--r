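# Peptide-to-protein mapping, peptide sequence queries, and the
# differential-mapping comparison used to infer splicing events from
# MS-detected peptides.

AA_LETTERS <- "ACDEFGHIKLMNPQRSTVWY"

.check_aa <- function(x) {
  if (!nzchar(x) || grepl(sprintf("[^%s]", AA_LETTERS), toupper(x)))
    stop("query contains non-amino-acid characters: ", x)
  toupper(x)
}

.read_proteins <- function(proteins) {
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins)) {
    aa <- Biostrings::readAAStringSet(proteins)
    seqs <- toupper(as.character(aa))
    names(seqs) <- vapply(strsplit(names(aa), "[ \t]"), `[[`, "", 1L)
    seqs
  } else {
    stopifnot(is.character(proteins), !is.null(names(proteins)))
    stats::setNames(toupper(proteins), names(proteins))
  }
}

#' Map peptides onto protein sequences
#'
#' Exact, case-insensitive substring search of every peptide against
#' every protein, reporting all (including overlapping) occurrences.
#' Isoleucine and leucine are NOT equated. Uses an Aho-Corasick
#' automaton, linear in total input size.
#'
#' @param peptides Peptide `data.frame` (columns `peptide_id`,
#'   `sequence`) as from [generate_peptides()].
#' @param proteins Path to a protein FASTA file (id = first header
#'   token), or a named character vector of sequences.
#' @return `data.frame` with columns `peptide_id`, `protein_id`,
#'   `offset` (1-based start of the peptide in the protein), ordered by
#'   (protein_id, offset, peptide_id).
#' @export
map_peptides_to_proteins <- function(peptides, proteins) {
  empty <- data.frame(peptide_id = character(0), protein_id = character(0),
                      offset = integer(0))
  if (nrow(peptides) == 0L) return(empty)
  prot <- .read_proteins(proteins)
  if (length(prot) == 0L) return(empty)
  seqs <- toupper(peptides$sequence)
  uniq <- unique(seqs)
  hits <- .ac_search(uniq, unname(prot))
  if (nrow(hits) == 0L) return(empty)
  # expand unique sequences back to the peptide ids sharing them
  by_seq <- split(peptides$peptide_id, match(seqs, uniq))
  reps <- lengths(by_seq)[as.character(hits$pattern)]
  out <- data.frame(
    peptide_id = unlist(by_seq[as.character(hits$pattern)], use.names = FALSE),
    protein_id = rep(names(prot)[hits$text], reps),
    offset = rep(hits$start, reps), stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$offset, out$peptide_id), ]
  rownames(out) <- NULL
  out
}

#' Search peptides for an amino-acid subsequence
#'
#' @param query Amino-acid string (standard 20 letters).
#' @param peptides Peptide `data.frame` (columns `peptide_id`,
#'   `sequence`, optionally `region_id`).
#' @param regions Optional region list; when given, region type and gene
#'   are attached to the result.
#' @return `data.frame` with columns `peptide_id`, `offset` (all
#'   occurrences), plus `region_id`/`region_type`/`gene_id` when
#'   available.
#' @export
search_sequence <- function(query, peptides, regions = NULL) {
  query <- .check_aa(query)
  empty <- data.frame(peptide_id = character(0), offset = integer(0))
  if (nrow(peptides) == 0L) return(empty)
  hits <- .ac_search(query, toupper(peptides$sequence))
  if (nrow(hits) == 0L) return(empty)
  out <- data.frame(peptide_id = peptides$peptide_id[hits$text],
                    offset = hits$start, stringsAsFactors = FALSE)
  if ("region_id" %in% names(peptides))
    out$region_id <- peptides$region_id[hits$text]
  if (!is.null(regions) && "region_id" %in% names(out)) {
    rt <- regions_table(regions)
    idx <- match(out$region_id, rt$region_id)
    out$region_type <- rt$region_type[idx]
    out$gene_id <- rt$gene_id[idx]
  }
  out <- out[order(out$peptide_id, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region chain of a protein
#'
#' Regions whose peptides map onto the given protein, in N-to-C order of
#' their first mapped offset (ties broken by region id). This is the
#' per-protein view used to read off exon/junction structure from
#' peptide evidence.
#'
#' @param protein_id Protein identifier.
#' @param hits Hit table from [map_peptides_to_proteins()].
#' @param peptides Peptide `data.frame` (to join peptide to region).
#' @param regions Optional region list for type annotation.
#' @return `data.frame` with columns `region_id`, `offset` (minimal
#'   offset of the region's peptides), plus `region_type` when
#'   `regions` is given.
#' @export
regions_for_protein <- function(protein_id, hits, peptides, regions = NULL) {
  h <- hits[hits$protein_id == protein_id, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(region_id = character(0), offset = integer(0)))
  h$region_id <- peptides$region_id[match(h$peptide_id, peptides$peptide_id)]
  off <- tapply(h$offset, h$region_id, min)
  out <- data.frame(region_id = names(off), offset = as.integer(off),
                    stringsAsFactors = FALSE)
  out <- out[order(out$offset, out$region_id), , drop = FALSE]
  if (!is.null(regions)) {
    rt <- regions_table(regions)
    out$region_type <- rt$region_type[match(out$region_id, rt$region_id)]
  }
  rownames(out) <- NULL
  out
}

#' Compare the protein mappings of two peptides
#'
#' Partitions the union of mapped proteins into shared / only-A /
#' only-B. When peptide A comes from a junction region and a protein
#' mapped only by B carries an additional region between the two regions
#' flanking A's junction, the explanation flags a candidate cassette
#' exon insertion naming that region: the inserted exon interrupts the
#' junction A straddles, so A's sequence cannot occur in that isoform.
#'
#' @param peptide_a,peptide_b Peptide ids.
#' @param hits Hit table from [map_peptides_to_proteins()].
#' @param peptides Peptide `data.frame`.
#' @param regions Optional region list (required for the cassette
#'   heuristic).
#' @return List of class `mapping_diff` with `proteins_only_a`,
#'   `proteins_only_b`, `proteins_shared`, `explanation` (character,
#'   possibly empty).
#' @export
diff_mappings <- function(peptide_a, peptide_b, hits, peptides,
                          regions = NULL) {
  stopifnot(peptide_a %in% peptides$peptide_id,
            peptide_b %in% peptides$peptide_id)
  prot_a <- unique(hits$protein_id[hits$peptide_id == peptide_a])
  prot_b <- unique(hits$protein_id[hits$peptide_id == peptide_b])
  res <- list(proteins_only_a = sort(setdiff(prot_a, prot_b)),
              proteins_only_b = sort(setdiff(prot_b, prot_a)),
              proteins_shared = sort(intersect(prot_a, prot_b)),
              explanation = character(0))
  if (!is.null(regions) && length(res$proteins_only_b)) {
    reg_a_id <- peptides$region_id[match(peptide_a, peptides$peptide_id)]
    reg_a <- Filter(function(r) identical(r$region_id, reg_a_id), regions)
    if (length(reg_a) == 1L && !is.na(reg_a[[1]]$junction_offset)) {
      flank <- reg_a[[1]]$source_exons
      # region ids of the exonic regions built on A's two source exons
      exon_region_of <- function(exon_id) {
        for (r in regions)
          if (r$region_type == "EXON_KB" && identical(r$source_exons, exon_id))
            return(r$region_id)
        NA_character_
      }
      flank_reg <- vapply(flank, exon_region_of, "")
      for (p in res$proteins_only_b) {
        chain <- regions_for_protein(p, hits, peptides, regions)
        chain <- chain[chain$region_type == "EXON_KB", , drop = FALSE]
        i5 <- match(flank_reg[1], chain$region_id)
        i3 <- match(flank_reg[2], chain$region_id)
        if (!is.na(i5) && !is.na(i3) && i3 - i5 > 1L) {
          inserted <- chain$region_id[(i5 + 1L):(i3 - 1L)]
          res$explanation <- c(
            res$explanation,
            sprintf("candidate cassette exon in %s: region(s) %s inserted between %s and %s",
                    p, paste(inserted, collapse = ","), flank_reg[1],
                    flank_reg[2]))
        }
      }
    }
  }
  class(res) <- "mapping_diff"
  res
}

#' @export
print.mapping_diff <- function(x, ...) {
  cat("<mapping_diff>\n",
      " only A : ", paste(x$proteins_only_a, collapse = ", "), "\n",
      " only B : ", paste(x$proteins_only_b, collapse = ", "), "\n",
      " shared : ", paste(x$proteins_shared, collapse = ", "), "\n", sep = "")
  for (e in x$explanation) cat(" note   : ", e, "\n", sep = "")
  invisible(x)
}
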