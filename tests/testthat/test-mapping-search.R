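pep_df <- function(seqs, region = NULL) {
  data.frame(peptide_id = sprintf("PEP%09d", seq_along(seqs)),
             region_id = if (is.null(region))
               sprintf("REG%09d", seq_along(seqs)) else region,
             sequence = seqs, is_wild_type = TRUE, snp_id = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("map_peptides_to_proteins finds all occurrences exactly", {
  prots <- c(p1 = "AGCDE", p2 = "AAA")
  hits <- map_peptides_to_proteins(pep_df(c("GCD", "AA")), prots)
  expect_equal(hits$protein_id, c("p1", "p2", "p2"))
  expect_equal(hits$offset, c(2L, 1L, 2L))   # overlapping occurrences

  # case-insensitive, I/L not equated
  hits2 <- map_peptides_to_proteins(pep_df("MIK"), c(p = "amikml"))
  expect_equal(hits2$offset, 2L)
  expect_equal(nrow(map_peptides_to_proteins(pep_df("MLK"),
                                             c(p = "AMIKML"))), 0L)
  # duplicate peptide sequences each get their own hit rows
  dup <- pep_df(c("AA", "AA"))
  expect_equal(nrow(map_peptides_to_proteins(dup, c(p = "CAAC"))), 2L)
  expect_equal(nrow(map_peptides_to_proteins(dup[0, ], prots)), 0L)
})

test_that("automaton agrees with a naive scan on random inputs", {
  withr::with_seed(31, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (rep in 1:10) {
      prots <- stats::setNames(
        vapply(1:5, function(i) paste(
          sample(aa[1:6], sample(20:60, 1), replace = TRUE),
          collapse = ""), ""),
        paste0("prot", 1:5))
      peps <- pep_df(vapply(1:12, function(i) paste(
        sample(aa[1:6], sample(2:4, 1), replace = TRUE), collapse = ""), ""))
      got <- map_peptides_to_proteins(peps, prots)
      want <- naive_map(peps, prots)
      rownames(want) <- NULL
      expect_equal(got, want)
    }
  })
})

test_that("search_sequence validates input and returns self-matches", {
  peps <- pep_df(c("MAGICK", "STANE"))
  expect_error(search_sequence("MA1K", peps), "non-amino-acid")
  expect_error(search_sequence("", peps), "non-amino-acid")
  self <- search_sequence("MAGICK", peps)
  expect_equal(self$peptide_id, "PEP000000001")
  expect_equal(self$offset, 1L)
  expect_equal(nrow(search_sequence("WWW", peps)), 0L)
  # every peptide finds itself
  for (i in seq_len(nrow(peps)))
    expect_true(peps$peptide_id[i] %in%
                  search_sequence(peps$sequence[i], peps)$peptide_id)
})

test_that("junction-spanning queries match only the junction peptide", {
  l <- locus(c("ATGGCAGCTAAA", "GGTCCTGAAACC"))
  gen <- generate_all(list(l$gene), l$adjacency, l$assembly)
  pep <- generate_peptides(gen$regions, l$exons[0, ])
  rt <- regions_table(gen$regions)
  pd <- pep$peptides
  pd_rt <- rt$region_type[match(pd$region_id, rt$region_id)]
  # exon1 MAAK | exon2 GPET; "KG" spans the junction
  hit <- search_sequence("KGP", pd, gen$regions)
  expect_true(all(hit$region_type %in% c("E_E_KB")))
  expect_gt(nrow(hit), 0L)
  # an exon-internal query hits the exon peptide too
  hit2 <- search_sequence("MAA", pd, gen$regions)
  expect_true("EXON_KB" %in% hit2$region_type)
})

test_that("regions_for_protein orders regions along the protein", {
  fx <- make_genome(n_genes = 1, seed = 51, exons_per_gene = c(3L, 3L),
                    exon_len = c(30L, 90L), out_dir = withr::local_tempdir())
  gen <- generate_all(fx$genes, build_exon_comb_kb(fx$genes), fx$assembly)
  pep <- generate_peptides(gen$regions, fx$snps[0, ])
  hits <- map_peptides_to_proteins(pep$peptides, fx$paths$proteins)
  pid <- names(fx$proteins)[1]
  chain <- regions_for_protein(pid, hits, pep$peptides, gen$regions)
  exonic <- chain[chain$region_type == "EXON_KB", ]
  expect_equal(nrow(exonic), 3L)                 # three exons, N-to-C
  expect_true(!is.unsorted(exonic$offset))
  # unknown protein -> empty
  expect_equal(nrow(regions_for_protein("nope", hits, pep$peptides)), 0L)
})

test_that("diff_mappings partitions proteins and is swap-symmetric", {
  peps <- pep_df(c("AAC", "CCD"))
  prots <- c(p1 = "AACCCD", p2 = "AACW", p3 = "WCCD")
  hits <- map_peptides_to_proteins(peps, prots)
  d <- diff_mappings("PEP000000001", "PEP000000002", hits, peps)
  expect_equal(d$proteins_only_a, "p2")
  expect_equal(d$proteins_only_b, "p3")
  expect_equal(d$proteins_shared, "p1")
  # partition property
  expect_setequal(c(d$proteins_only_a, d$proteins_only_b,
                    d$proteins_shared), c("p1", "p2", "p3"))
  d2 <- diff_mappings("PEP000000002", "PEP000000001", hits, peps)
  expect_equal(d2$proteins_only_a, d$proteins_only_b)
  expect_equal(d2$proteins_only_b, d$proteins_only_a)
  expect_equal(d2$proteins_shared, d$proteins_shared)
  # identical and disjoint mappings
  same <- diff_mappings("PEP000000001", "PEP000000001", hits, peps)
  expect_length(same$proteins_only_a, 0L)
  expect_length(same$proteins_only_b, 0L)
})

test_that("cassette-exon isoforms are explained from peptide evidence", {
  out <- withr::local_tempdir()
  fx <- make_genome(n_genes = 1, seed = 77, exons_per_gene = c(3L, 3L),
                    exon_len = c(30L, 90L), cassette = TRUE, out_dir = out)
  g <- fx$genes[[1]]
  gen <- generate_all(fx$genes, build_exon_comb_kb(fx$genes), fx$assembly)
  pep <- generate_peptides(gen$regions, fx$snps[0, ])
  hits <- map_peptides_to_proteins(pep$peptides, fx$paths$proteins)
  cass <- fx$truth$genes[[1]]$cassette_exon
  ci <- match(cass, g$exons$exon_id)
  e5 <- g$exons$exon_id[ci - 1L]
  e3 <- g$exons$exon_id[ci + 1L]
  skip_junction <- Filter(function(r) r$region_type == "E_E_KB" &&
                            identical(r$source_exons, c(e5, e3)),
                          gen$regions)[[1]]
  shared_exon <- Filter(function(r) r$region_type == "EXON_KB" &&
                          identical(r$source_exons, e3), gen$regions)[[1]]
  pd <- pep$peptides
  pa <- pd$peptide_id[pd$region_id == skip_junction$region_id]
  pb <- pd$peptide_id[pd$region_id == shared_exon$region_id]
  d <- diff_mappings(pa, pb, hits, pd, gen$regions)
  # the cassette-bearing isoform is mapped by the exon peptide only
  cass_prot <- paste0("P_", names(g$transcripts)[1])  # t1 contains all exons
  expect_true(cass_prot %in% d$proteins_only_b)
  cass_region <- Filter(function(r) r$region_type == "EXON_KB" &&
                          identical(r$source_exons, cass), gen$regions)[[1]]
  expect_length(d$explanation, 1L)
  expect_match(d$explanation, cass_region$region_id, fixed = TRUE)
})
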