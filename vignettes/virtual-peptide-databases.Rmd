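---
title: "Virtual peptide databases for protein isoform identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual peptide databases for protein isoform identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicepep)
```

## The problem

A shotgun proteomics experiment identifies peptides by matching tandem
mass spectra against a sequence database. If the database holds only
annotated protein sequences, any spectrum produced by an unannotated
isoform — a skipped exon, a retained intron, an unannotated exon pair,
or a non-synonymous SNP — cannot be matched. `splicepep` inverts the
problem: instead of asking which annotated proteins are present, it
enumerates from the genome every peptide that *could* be observed
under a family of splicing hypotheses, producing an MS-searchable
FASTA plus the bookkeeping (region tables, peptide–SNP maps,
peptide–protein maps) needed to interpret a hit afterwards.

## The model

### Coordinates and gene representation

All coordinates are 1-based and inclusive (the shared convention of
GFF3, VCF and Ensembl exports). "Exon" always means the coding (CDS)
part of an exon; UTRs are excluded at read time, which has the same
effect as carrying a separate UTR table but needs one fewer input.
Each coding exon carries a `frame_offset` with GFF3 phase semantics:
the number of 5′ bases to skip so translation starts on a codon
boundary. When importing Ensembl-style start-phases *p*, convert with
`(3 - p) mod 3`.

Two knowledgebases are derived from the coding-filtered annotation
(`filter_coding_genes`: a gene is coding iff it maps to ≥ 1 protein,
via `protein_id` attributes or an external two-column table):

* the **exon knowledgebase** — all distinct coding exons, gene-scoped;
* the **adjacency knowledgebase** — all ordered exon pairs that occur
  consecutively in any annotated transcript.

SNPs are restricted to those inside coding exons (inclusive
boundaries). A SNP whose reference allele disagrees with the genome is
kept with a warning rather than dropped: variation and assembly
releases legitimately drift apart, and variant application substitutes
the alternate allele regardless of what the reference claims.

### Region enumeration

Five region types are generated per gene (`generate_all`), each with
its own validation protocol:

* **EXON_KB** — the whole exon, translated in its annotated frame.
* **E_E_KB** — each adjacency, joining the last ≤ 120 nt of the 5′
  exon to the first ≤ 120 nt of the 3′ exon. The frame is propagated
  from the 5′ exon: a segment starting `trim` bases into the exon
  translates with offset `(frame − trim) mod 3`
  (`segment_frame_offset`).
* **E_I_TH / I_E_TH** — each exon joined to its immediately adjacent
  downstream/upstream intron (the gap between consecutive exons of the
  gene-level, transcription-ordered exon list; abutting exons yield no
  intron), all three frames.
* **E_E_TH** — every ordered within-gene exon pair that is (a)
  strictly downstream in transcription order, (b) genomically
  non-overlapping, and (c) absent from the adjacency knowledgebase,
  all three frames. Overlapping pairs are excluded because mutually
  exclusive exon variants cannot co-occur in one mature transcript;
  enumeration stays within one gene (no fusions, no triples).

The 120-nt flank is the package's central tunable
(`region_config(flank_nt = )`). Its default derives from the longest
peptide plausibly identified in an MS experiment — 80 aa, i.e.
240 nt — so a junction window of 120 + 120 nt contains every
junction-crossing peptide whose shorter side does not exceed 40
residues.

### Stop-codon protocols

Translation uses the standard genetic code; codons containing
ambiguous bases become `X`, and any peptide retaining an `X` is
discarded (`ambiguous`) since MS search cannot match it. Stops are
handled per type:

* A stop as the **final codon** of a region is read as the natural
  C-terminus: it is stripped and the region kept. Discarding instead
  would lose every 3′-terminal exon of every gene.
* EXON_KB, E_E_KB and I_E_TH tolerate no other stop
  (`internal_stop`).
* E_I_TH and E_E_TH tolerate a stop **in the 3′ segment**: the peptide
  is truncated immediately before it. A codon straddling the junction
  is attributed to the 3′ segment when at least one of its bases lies
  there — the protocol names a segment, not a codon rule, and this is
  the minimal consistent reading. A stop wholly inside the 5′ exon
  segment rejects the frame (`stop_in_5prime`).
* After any truncation or stripping, a junction peptide must still
  cover ≥ 1 residue on each side of the splice site
  (`junction_not_covered`); a non-crossing remnant would only
  duplicate EXON_KB content, which is the reason junction regions
  exist at all. This check is applied uniformly to all four junction
  types.

Rejected candidates are data, not errors: every one is recorded in a
rejection log with its reason, and "candidates = kept + rejected" is
what the closed-form count tests check. Peptides are never
deduplicated across regions — mapping semantics need per-region
identity. A minimum peptide length is configurable
(`min_peptide_len`, default 1 = keep everything; no minimum is imposed
by the method itself).

Output ordering is fully deterministic: genes alphabetically, types in
the order EXON_KB, E_E_KB, E_I_TH, I_E_TH, E_E_TH, then genomic start
of the 5′ and 3′ segments, then frame; serial ids `REG000000001…` /
`PEP000000001…` are assigned in that order. No attempt is made to
reproduce any historical id values, which depended on a particular
annotation release's ordering.

### SNP variant peptides

For each region, each exonic SNP allele falling inside an *exon-role*
segment (intron segments take no SNPs) is substituted individually —
one SNP per variant peptide, no haplotype combinations, matching the
additive per-SNP accounting of this database family and avoiding
combinatorial blow-up. The variant cDNA is re-validated under the
region's own protocol; variants whose peptide equals the wild type are
rejected as synonymous (non-synonymy is decided by comparing the
translated sequences, not by annotation flags, so the pipeline is
self-contained). A variant that introduces a *tolerated* 3′-segment
stop and truncates the peptide is kept when the sequence changes: a
changed sequence is observable by MS. On minus-strand regions alleles
are complemented into region orientation, and each variant records its
nucleotide change and amino-acid change (`aa_change`, e.g. `R25S`).

### Mapping, search, and isoform inference

Peptide→protein mapping is exact substring search (case-insensitive,
I/L **not** equated — mass ambiguity belongs to the search engine, not
the database), reporting all, including overlapping, occurrences. It
runs on an Aho–Corasick automaton (Rcpp), linear in total input plus
output size; tests cross-check it against a naive scan.

`diff_mappings` partitions the proteins mapped by two peptides into
shared/only-A/only-B. When A is a junction peptide and a protein
mapped only by B shows an extra exonic region between the two regions
flanking A's junction, the result is annotated as a candidate cassette
exon naming that region. This is deliberately a heuristic annotation,
not a verdict, and fires only on the single-inserted-region topology;
a full alternative-splicing event taxonomy is out of scope.

### Decoys and FDR

Decoy databases reverse each sequence whole and prefix ids with
`DECOY_` (no cleavage-site-preserving pseudo-reversal — the method
this package follows specifies plain inverse sequences). Two
estimators are provided: `fdr_simple` = d/(t+d) and
`fdr_concatenated` = 2d/(t+d) capped at 1 (the cap because 2d can
exceed t+d and FDR is a proportion). The per-level assignment —
simple at the peptide level, concatenated at the spectrum,
protein/gene and database-peptide levels — was recovered by
arithmetic from the published worked example this package reproduces,
whose table states no formula; both estimators are exported so either
can be applied anywhere. Of note, the protein/gene row of that
example reproduces from its *gene* counts (141 targets, 2 decoys →
0.02797), not its protein counts. Supporting utilities implement the
at-least-two-distinct-samples reproducibility filter and a standard
threshold sweep (sort by E-value, keep the largest prefix whose
estimated FDR stays at or below the request).

## The synthetic world

`make_genome` emulates compact eukaryotic loci: 3–5 coding exons of
30–120 nt, introns of 20–60 nt, both strands, valid phase chaining,
60-nt flanks, and (optionally) a second transcript skipping one middle
exon. Defaults were chosen once as structurally realistic at test
scale — real human exons average ~145 nt with much longer introns, but
the protocols under test depend on exon/intron *topology* and codon
arithmetic, not on length statistics. What the generator does **not**
emulate: realistic gene length distributions, GC content, splice-site
motifs, overlapping genes, shared exons between genes, or EST-style
noise. A green test therefore establishes protocol correctness
(enumeration, frames, stop handling, coordinate arithmetic, strand
symmetry), not performance on genome-scale human data.

Specifics worth knowing:

* With `stop_free = TRUE` coding sequence is drawn from the 61 sense
  codons, so the annotated frame translates cleanly; hypothetical
  frames still hit stops at random, exercising the rejection paths.
  The total CDS length is padded to a codon multiple.
* With `cassette = TRUE` all exon lengths are rounded to codon
  multiples so both transcripts share one phase assignment per exon —
  the package's exon model (one frame per coding exon) requires it.
* SNPs are planted only at codons lying wholly inside one exon and
  never at an exon's last complete codon, and their consequence
  (synonymous / non-synonymous / stop-introducing) is computed at
  plant time by direct codon translation, independent of the code
  under test. The last-codon exclusion keeps the truth mapping exact:
  a stop in the final codon would be stripped as a natural terminus
  rather than rejected.
* The brute-force oracle (`oracle_enumerate`) re-derives the protocols
  with its own hard-coded codon table, its own reverse-complement and
  a codon-by-codon scan; equivalence with `generate_all` over hundreds
  of seeded random genomes is the repository's central correctness
  property.

## Numerical and design choices

* **Coverage guarantee testing.** The guarantee "every ≤ 80-aa
  junction-crossing peptide is captured" is tested on fixtures whose
  exons fit entirely inside the 120-nt flanks. With longer exons the
  literal universal claim is geometrically unattainable: an 80-aa
  peptide split 79 + 1 across a junction needs 237 nt on its long
  side, twice the window. The window guarantees capture of crossings
  with ≤ 40 residues on the shorter side; the test fixtures make the
  two statements coincide.
* **Degenerate inputs.** Abutting gene-level exons generate no intron
  regions; single-exon genes generate no junctions of any kind; an
  empty gene list yields empty, header-only outputs. Frames whose
  segment is shorter than one codon are rejected as `too_short`.
* **Ties and ordering.** All orderings are total (documented sort
  keys), so reruns are byte-identical — asserted by test.
* **Performance.** Reverse-complement and translation are plain
  vectorized character operations (the codon table is taken from
  Biostrings' `GENETIC_CODE`); heavyweight sequence containers are
  used at file boundaries only. This keeps exhaustive enumeration over
  hundreds of random genomes within a test budget of about a minute.

## Limitations

Indels, multi-nucleotide variants, splice-site-disrupting variants and
haplotype phasing are out of scope; so are exon triples, cross-gene
fusions, intron–intron junctions, probabilistic protein inference and
running any search engine. Chromosome names are matched exactly (no
synonym resolution). The package reproduces the *method* — region
protocols, variant insertion, mapping and FDR arithmetic — at fixture
scale; the published human-genome database sizes depend on a specific
historical annotation release and protein catalogue and are not
reproduction targets.
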