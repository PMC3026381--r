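test_that("segment_frame_offset realigns trimmed segments", {
  expect_equal(segment_frame_offset(0, 3), 0L)
  expect_equal(segment_frame_offset(0, 2), 1L)  # first boundary >= 2 is 3
  expect_equal(segment_frame_offset(2, 0), 2L)
  # property: skipping the returned offset lands on an exon codon boundary
  for (f in 0:2) for (trim in 0:7) {
    s <- segment_frame_offset(f, trim)
    expect_equal((trim + s - f) %% 3, 0)
  }
})

test_that("exonic regions follow the stop protocol", {
  l <- locus("ATGGCAGGG")
  res <- gen_exon_region(l$exons[1, ], l$gene, l$assembly)
  expect_length(res$regions, 1L)
  expect_equal(res$regions[[1]]$wild_peptide, "MAG")
  expect_equal(res$regions[[1]]$cdna, "ATGGCAGGG")

  l <- locus("ATGTAAGGG")
  res <- gen_exon_region(l$exons[1, ], l$gene, l$assembly)
  expect_length(res$regions, 0L)
  expect_equal(res$rejections$reason, "internal_stop")

  l <- locus("ATGGGGTAA")
  res <- gen_exon_region(l$exons[1, ], l$gene, l$assembly)
  expect_equal(res$regions[[1]]$wild_peptide, "MG")  # terminal stop stripped

  # ambiguous bases invalidate
  l <- locus("ATGNNNGGG")
  res <- gen_exon_region(l$exons[1, ], l$gene, l$assembly)
  expect_equal(res$rejections$reason, "ambiguous")
})

test_that("annotated exon-exon junctions use 120-nt flanks and the 5' frame", {
  l <- locus(c("ATGGCA", "GGGTAG"))
  ex <- l$exons
  res <- gen_eekb_region(ex[1, ], ex[2, ], l$gene, l$assembly)
  r <- res$regions[[1]]
  expect_equal(r$wild_peptide, "MAG")     # terminal stop stripped
  expect_equal(r$orf, 0L)
  expect_equal(r$junction_offset, 6)
  expect_equal(r$segments$role, c("exon5", "exon3"))

  # long exons are trimmed to 120 nt per side
  long5 <- paste(rep("GCT", 100), collapse = "")   # 300 nt
  short3 <- paste(rep("GGT", 16), collapse = "")   # 48 nt
  l <- locus(c(long5, short3))
  res <- gen_eekb_region(l$exons[1, ], l$exons[2, ], l$gene, l$assembly)
  r <- res$regions[[1]]
  expect_equal(nchar(r$cdna), 120 + 48)
  expect_equal(nchar(r$wild_peptide), (120 + 48) / 3)
  # trimmed frame still aligns with annotated codons (Ala/Gly only)
  expect_true(grepl("^A+G+$", r$wild_peptide))

  # junction-spanning stop codon (TA|A) in frame is fatal
  l <- locus(c("ATGGCATA", "AGGGGGG"))
  res <- gen_eekb_region(l$exons[1, ], l$exons[2, ], l$gene, l$assembly)
  expect_length(res$regions, 0L)
  expect_equal(res$rejections$reason, "internal_stop")
})

test_that("exon-intron junctions tolerate intron stops by truncation", {
  l <- locus(c("ATGGCA", "CCCCCC"), intron_seqs = "GTTAACGGTGGT")
  intron <- c(l$exons$end[1] + 1L, l$exons$start[2] - 1L)
  res <- gen_eith_regions(l$exons[1, ], intron, l$gene, l$assembly)
  pep0 <- Filter(function(r) r$orf == 0L, res$regions)[[1]]
  expect_equal(pep0$wild_peptide, "MAVNGG")        # no stop anywhere

  # stop immediately after the junction truncates to the exon side only:
  # the remnant no longer crosses the junction and the frame is dropped
  l <- locus(c("ATGGCA", "CCCCCC"), intron_seqs = "TAAGGGGGGGGG")
  intron <- c(l$exons$end[1] + 1L, l$exons$start[2] - 1L)
  res <- gen_eith_regions(l$exons[1, ], intron, l$gene, l$assembly)
  rej0 <- res$rejections[res$rejections$orf == 0L, ]
  expect_equal(rej0$reason, "junction_not_covered")

  # a stop wholly inside the exon segment rejects the frame outright
  l <- locus(c("TAAGCA", "CCCCCC"), intron_seqs = "GGGGGGGGGGGG")
  intron <- c(l$exons$end[1] + 1L, l$exons$start[2] - 1L)
  res <- gen_eith_regions(l$exons[1, ], intron, l$gene, l$assembly)
  rej0 <- res$rejections[res$rejections$orf == 0L, ]
  expect_equal(rej0$reason, "stop_in_5prime")
})

test_that("intron-exon junctions do not tolerate stops", {
  l <- locus(c("CCCCCC", "ATGGCA"), intron_seqs = "CCCCCC")
  intron <- c(l$exons$end[1] + 1L, l$exons$start[2] - 1L)
  res <- gen_ieth_regions(intron, l$exons[2, ], l$gene, l$assembly)
  pep0 <- Filter(function(r) r$orf == 0L, res$regions)[[1]]
  expect_equal(pep0$wild_peptide, "PPMA")

  # intron CCTAAC: the TAA lies in frame 2 only
  l <- locus(c("CCCCCC", "ATGGCA"), intron_seqs = "CCTAAC")
  intron <- c(l$exons$end[1] + 1L, l$exons$start[2] - 1L)
  res <- gen_ieth_regions(intron, l$exons[2, ], l$gene, l$assembly)
  expect_equal(res$rejections$reason[res$rejections$orf == 2L],
               "internal_stop")                    # TAA CAT GGC
  pep0 <- Filter(function(r) r$orf == 0L, res$regions)[[1]]
  expect_equal(pep0$wild_peptide, "PNMA")          # CCT AAC ATG GCA
  pep1 <- Filter(function(r) r$orf == 1L, res$regions)[[1]]
  expect_equal(pep1$wild_peptide, "LTW")           # CTA ACA TGG
})

test_that("hypothetical exon pairs exclude annotated and overlapping pairs", {
  # 4-exon single-transcript gene: C(4,2)=6 pairs minus 3 annotated
  seqs <- c("ATGGCAGCT", "GCTGCAACC", "ACCGCTGCA", "GCAACCGCT")
  l <- locus(seqs)
  res <- gen_eeth_regions(l$gene, l$adjacency, l$assembly)
  cand <- length(res$regions) +
    (if (is.null(res$rejections)) 0L else nrow(res$rejections))
  expect_equal(cand, 3L * 3L)
  got_pairs <- unique(vapply(res$regions, function(r)
    paste(r$source_exons, collapse = "+"), ""))
  expect_true(all(got_pairs %in% c("g1.e1+g1.e3", "g1.e1+g1.e4",
                                   "g1.e2+g1.e4")))

  # two-exon single-transcript gene: the only pair is annotated
  l2 <- locus(c("ATGGCA", "GGTGGT"))
  res2 <- gen_eeth_regions(l2$gene, l2$adjacency, l2$assembly)
  expect_length(res2$regions, 0L)
  expect_null(res2$rejections)

  # overlapping alternative exons can never pair
  ex <- data.frame(exon_id = c("a", "b"), chrom = "cO",
                   start = c(10L, 15L), end = c(30L, 35L), strand = "+",
                   frame_offset = 0L, stringsAsFactors = FALSE)
  g <- gene_model("gO", chrom = "cO", strand = "+", exons = ex,
                  transcripts = list(t1 = "a", t2 = "b"),
                  protein_ids = "P")
  asm <- genome_assembly(c(cO = paste(rep("ACG", 20), collapse = "")))
  res3 <- gen_eeth_regions(g, build_exon_comb_kb(list(g)), asm)
  expect_length(res3$regions, 0L)
  expect_null(res3$rejections)
})

test_that("generate_all is deterministic, ordered and serially numbered", {
  fx <- make_genome(n_genes = 3, seed = 99)
  adj <- build_exon_comb_kb(fx$genes)
  g1 <- generate_all(fx$genes, adj, fx$assembly)
  g2 <- generate_all(fx$genes, adj, fx$assembly)
  expect_identical(g1, g2)
  ids <- vapply(g1$regions, `[[`, "", "region_id")
  expect_equal(ids, sprintf("REG%09d", seq_along(ids)))
  # sorted by gene, then type rank, then 5' segment start
  rt <- regions_table(g1$regions)
  key <- order(rt$gene_id,
               match(rt$region_type,
                     c("EXON_KB", "E_E_KB", "E_I_TH", "I_E_TH", "E_E_TH")))
  expect_equal(key, seq_len(nrow(rt)))
  expect_identical(generate_all(list(), adj, fx$assembly)$regions, list())
})

test_that("wild peptides never contain stops or ambiguity; junctions <= 240 nt", {
  fx <- make_genome(n_genes = 3, seed = 17, stop_free = FALSE,
                    exon_len = c(30L, 200L))
  adj <- build_exon_comb_kb(fx$genes)
  gen <- generate_all(fx$genes, adj, fx$assembly)
  rt <- regions_table(gen$regions)
  expect_false(any(grepl("[*X]", rt$wild_peptide)))
  junc <- rt[rt$region_type != "EXON_KB", ]
  expect_true(all(nchar(junc$cdna) <= 240))
  exonic <- rt[rt$region_type == "EXON_KB", ]
  expect_true(all(nchar(exonic$cdna) >= 30))
  # junction peptides genuinely cross the splice site
  for (r in gen$regions) {
    if (is.na(r$junction_offset)) next
    first0 <- r$orf
    last0 <- r$orf + 3L * nchar(r$wild_peptide) - 1L
    expect_true(first0 < r$junction_offset && last0 >= r$junction_offset)
  }
})

test_that("stop toleration asymmetry: E_I_TH survives more often than I_E_TH", {
  kept_ei <- 0L
  kept_ie <- 0L
  for (seed in 1:6) {
    fx <- make_genome(n_genes = 2, seed = 4000 + seed, stop_free = FALSE)
    gen <- generate_all(fx$genes, build_exon_comb_kb(fx$genes), fx$assembly)
    rt <- regions_table(gen$regions)
    kept_ei <- kept_ei + sum(rt$region_type == "E_I_TH")
    kept_ie <- kept_ie + sum(rt$region_type == "I_E_TH")
  }
  expect_gt(kept_ei, kept_ie)
})
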