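test_that("place_snps respects segments, flanks and strand", {
  # 300-nt exon: only the last 120 nt are inside an E-E junction flank
  long5 <- paste(rep("GCT", 100), collapse = "")
  l <- locus(c(long5, "GGTGGTGGT"))
  res <- gen_eekb_region(l$exons[1, ], l$exons[2, ], l$gene, l$assembly)
  r <- res$regions[[1]]
  in_flank <- data.frame(snp_id = "s1", chrom = "chrT",
                         pos = l$exons$end[1] - 5L, ref = "C", alt = "A",
                         stringsAsFactors = FALSE)
  before_flank <- data.frame(snp_id = "s2", chrom = "chrT",
                             pos = l$exons$start[1] + 5L, ref = "C",
                             alt = "A", stringsAsFactors = FALSE)
  expect_equal(nrow(place_snps(r, in_flank)), 1L)
  expect_equal(nrow(place_snps(r, before_flank)), 0L)

  # intron segment of an E_I_TH region takes no SNPs
  l2 <- locus(c("ATGGCA", "CCCCCC"), intron_seqs = "GGTGGTGGTGGT")
  intron <- c(l2$exons$end[1] + 1L, l2$exons$start[2] - 1L)
  ei <- gen_eith_regions(l2$exons[1, ], intron, l2$gene, l2$assembly)
  r2 <- ei$regions[[1]]
  in_intron <- data.frame(snp_id = "s3", chrom = "chrT",
                          pos = l2$exons$end[1] + 3L, ref = "G", alt = "A",
                          stringsAsFactors = FALSE)
  expect_equal(nrow(place_snps(r2, in_intron)), 0L)

  # minus strand: forward alleles are complemented into region orientation
  lm <- locus("ATGGCAGGG", strand = "-")
  rm_ <- gen_exon_region(lm$exons[1, ], lm$gene, lm$assembly)$regions[[1]]
  expect_equal(rm_$cdna, "ATGGCAGGG")
  # local position 5 is 'C'; its forward-strand base is G
  gpos <- lm$exons$end[1] - 5L + 1L
  snp <- data.frame(snp_id = "s4", chrom = "chrT", pos = gpos, ref = "G",
                    alt = "A", stringsAsFactors = FALSE)
  pl <- place_snps(rm_, snp)
  expect_equal(pl$local_pos, 5L)
  expect_equal(pl$ref_local, "C")
  expect_equal(pl$alt_local, "T")
})

test_that("apply_snp classifies substitutions through the region protocol", {
  l <- locus("ATGGCA")
  r <- gen_exon_region(l$exons[1, ], l$gene, l$assembly)$regions[[1]]
  expect_equal(r$wild_peptide, "MA")
  pl <- function(pos, ref, alt) data.frame(
    snp_id = "s", local_pos = pos, genomic_pos = l$exons$start[1] + pos - 1L,
    ref_local = ref, alt_local = alt, stringsAsFactors = FALSE)
  res <- apply_snp(r, pl(5, "C", "A"))            # GCA -> GAA
  expect_equal(res$status, "ok")
  expect_equal(res$sequence, "ME")
  expect_equal(c(res$aa_pos, res$aa_ref, res$aa_alt), c("2", "A", "E"))

  expect_equal(apply_snp(r, pl(6, "A", "G"))$status, "synonymous")  # GCG = Ala

  l2 <- locus("ATGTGCAAA")
  r2 <- gen_exon_region(l2$exons[1, ], l2$gene, l2$assembly)$regions[[1]]
  expect_equal(r2$wild_peptide, "MCK")
  pl2 <- data.frame(snp_id = "s", local_pos = 6L, genomic_pos = 0L,
                    ref_local = "C", alt_local = "A",
                    stringsAsFactors = FALSE)
  expect_equal(apply_snp(r2, pl2)$status, "invalid_peptide")  # TGA stop

  # reference disagreement warns but substitutes
  plw <- data.frame(snp_id = "s", local_pos = 5L, genomic_pos = 0L,
                    ref_local = "G", alt_local = "A",
                    stringsAsFactors = FALSE)
  expect_warning(resw <- apply_snp(r, plw), "expected")
  expect_equal(resw$sequence, "ME")
})

test_that("generate_peptides emits wild type first and one entry per variant", {
  # region with no placements -> wild type only
  l <- locus("ATGGCAGGG")
  gen <- generate_all(list(l$gene), l$adjacency, l$assembly)
  none <- generate_peptides(gen$regions, l$gene$exons[0, ])
  expect_equal(nrow(none$peptides), length(gen$regions))
  expect_true(all(none$peptides$is_wild_type))
  expect_equal(none$peptides$peptide_id,
               sprintf("PEP%09d", seq_len(nrow(none$peptides))))

  # two non-synonymous SNPs -> 3 peptides for that region
  snps <- data.frame(snp_id = c("a", "b"), chrom = "chrT",
                     pos = l$exons$start[1] + c(1L, 4L), ref = c("T", "C"),
                     alt = c("G", "A"), stringsAsFactors = FALSE)
  out <- generate_peptides(gen$regions[1], snps)
  expect_equal(nrow(out$peptides), 3L)
  expect_equal(sum(out$peptides$is_wild_type), 1L)
  expect_equal(nrow(out$snp_map), 2L)

  # tri-allelic SNP: GGG codon, G>A at position 3 changes (GGA=G? no: GGA=G)
  # use codon AAA (Lys): A>G at pos 3 -> AAG (Lys, synonymous);
  # A>C at pos 3 -> AAC (Asn, non-synonymous)
  l3 <- locus("ATGAAA")
  gen3 <- generate_all(list(l3$gene), l3$adjacency, l3$assembly)
  tri <- data.frame(snp_id = "t", chrom = "chrT",
                    pos = l3$exons$start[1] + 5L, ref = "A",
                    alt = c("G", "C"), stringsAsFactors = FALSE)
  out3 <- generate_peptides(gen3$regions, tri)
  expect_equal(nrow(out3$peptides), 2L)   # wild + one non-synonymous
  expect_equal(out3$rejections$status, "synonymous")

  # determinism of ids
  again <- generate_peptides(gen3$regions, tri)
  expect_identical(out3, again)
})

test_that("variant peptides differ from wild type as claimed", {
  fx <- make_genome(n_genes = 3, seed = 23)
  adj <- build_exon_comb_kb(fx$genes)
  gen <- generate_all(fx$genes, adj, fx$assembly)
  out <- generate_peptides(gen$regions, fx$snps)
  wild_of <- stats::setNames(
    out$peptides$sequence[out$peptides$is_wild_type],
    out$peptides$region_id[out$peptides$is_wild_type])
  vars <- out$peptides[!out$peptides$is_wild_type, ]
  expect_gt(nrow(vars), 0L)
  for (i in seq_len(nrow(vars))) {
    w <- wild_of[[vars$region_id[i]]]
    v <- vars$sequence[i]
    expect_false(identical(w, v))
    if (nchar(w) == nchar(v)) {
      # non-truncating substitution changes exactly one residue
      expect_equal(sum(strsplit(w, "")[[1]] != strsplit(v, "")[[1]]), 1L)
    }
  }
  # placements can only shrink into peptides
  for (r in gen$regions) {
    n_pl <- nrow(place_snps(r, fx$snps))
    n_var <- sum(vars$region_id == r$region_id)
    expect_lte(n_var, n_pl)
  }
})
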