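# splicepep

Exhaustive virtual-peptide databases for protein isoform identification
by shotgun mass spectrometry.

Standard MS search databases (UniProt-style protein FASTA) carry only
annotated protein sequences, so spectra produced by unannotated splice
variants or coding SNPs go unidentified. `splicepep` expands the search
space from the genome itself: it enumerates, for every protein-coding
gene, all peptide *regions* that could be observed —

| type      | meaning                                         | cDNA length | reading frame           | stop codons                 |
|-----------|--------------------------------------------------|-------------|-------------------------|------------------------------|
| `EXON_KB` | annotated coding exon                           | whole exon  | annotated frame         | not tolerated                |
| `E_E_KB`  | annotated exon–exon junction                    | ≤ 240 nt    | annotated 5′-exon frame | not tolerated                |
| `E_I_TH`  | hypothetical exon–intron junction (intron retention) | ≤ 240 nt | all 3 frames            | tolerated in the 3′ segment  |
| `I_E_TH`  | hypothetical intron–exon junction               | ≤ 240 nt    | all 3 frames            | not tolerated                |
| `E_E_TH`  | hypothetical (unannotated) exon–exon junction   | ≤ 240 nt    | all 3 frames            | tolerated in the 3′ segment  |

Junction cDNAs take at most 120 nt from each side of the splice site
(240 nt = 80 aa, the longest peptide realistically observable in an MS
experiment), so any junction-crossing peptide up to that flank size is
guaranteed to occur in the database. A stop codon as the final codon of
a region is treated as a natural C-terminus and stripped; a "tolerated"
stop truncates the peptide, which is kept only while it still crosses
the splice site. Each region additionally yields one variant peptide
per non-synonymous exonic SNP (single-SNP substitution, re-validated
under the region's own protocol).

On top of the generator the package provides:

* peptide → protein mapping (exact substring, Aho–Corasick, all
  occurrences) and peptide-sequence queries;
* differential mapping of two peptides across a protein set, with a
  cassette-exon explanation for the junction-peptide-missing topology;
* reversed `DECOY_` database construction and multi-level target–decoy
  FDR arithmetic: `d/(t+d)` at the peptide level, `2d/(t+d)` at the
  spectrum, protein/gene and database-peptide levels, plus a
  two-distinct-samples reproducibility filter and an E-value sweep to a
  requested FDR;
* a seeded synthetic genome/GFF3/VCF generator with ground truth and an
  independent brute-force oracle used to cross-validate the generator.

## Worked example

```r
library(splicepep)

# a seeded synthetic 3-exon gene with planted SNPs (writes FASTA/GFF3/VCF)
fx  <- make_genome(n_genes = 1, exons_per_gene = c(3, 3), seed = 11,
                   out_dir = tempfile())
adj <- build_exon_comb_kb(fx$genes)
gen <- generate_all(fx$genes, adj, fx$assembly)
pep <- generate_peptides(gen$regions, fx$snps)
write_tables(tempfile(), gen$regions, pep$peptides, pep$snp_map,
             rejections = gen$rejections)
```

```
EXON_KB  regions/wild peptides:      3  SNP peptides:      1  all:      4
E_E_KB   regions/wild peptides:      2  SNP peptides:      2  all:      4
E_I_TH   regions/wild peptides:      2  SNP peptides:      1  all:      3
I_E_TH   regions/wild peptides:      1  SNP peptides:      0  all:      1
E_E_TH   regions/wild peptides:      2  SNP peptides:      1  all:      3
```

Three exons give 3 `EXON_KB` regions and 2 annotated junctions; the
hypothetical candidates (6 `E_I_TH`, 6 `I_E_TH`, 3 `E_E_TH` frames)
are thinned by the stop-codon protocols to 2/1/2 surviving regions.
The regions table shows the serial ids, frames and genomic segments:

```r
head(regions_table(gen$regions)[, c("region_id", "region_type", "orf",
                                    "loc", "wild_peptide")], 4)
#      region_id region_type orf            loc                                    wild_peptide
# 1 REG000000001     EXON_KB   2         61-116                              SDLSVNFLPDGCVTLMDN
# 2 REG000000002     EXON_KB   0        144-228                    LTPGIIELDCLIHGHNLYRATAKYRTPR
# 3 REG000000003     EXON_KB   0        276-338                           GMSRADSPRTRSICETRLMSA
# 4 REG000000004      E_E_KB   0 144-228|61-116 LTPGIIELDCLIHGHNLYRATAKYRTPRFSDLSVNFLPDGCVTLMDN
```

(the gene is on the minus strand, so transcription order runs right to
left along the chromosome). The peptide–SNP map records each variant's
nucleotide and amino-acid change; the same SNP appears once per region
containing it, e.g. `rs0002` as `R25S` in the exon region and `R46S` in
a junction region where the peptide starts further upstream:

```r
head(pep$snp_map, 3)
#     peptide_id snp_id local_pos genomic_pos nt_change aa_change
# 1 PEP000000003 rs0002        75         154       G>C      R25S
# 2 PEP000000006 rs0002        75         154       G>C      R25S
# 3 PEP000000008 rs0002       138         154       G>C      R46S
```

Target–decoy FDR from a hit table (99 target and 1 decoy spectra):

```r
summarize_fdr(hits, "ms2")
# <fdr_summary> level=ms2          targets=99 decoys=1 FDR=0.02000
```

The same pipeline is scriptable end to end:

```sh
Rscript -e 'splicepep::splicepep_cli()' simulate --seed 3 --out fx
Rscript -e 'splicepep::splicepep_cli()' build --genome fx/genome.fasta \
    --gff fx/annotation.gff3 --vcf fx/snps.vcf --out db --preset PEPPI_with_SNP
Rscript -e 'splicepep::splicepep_cli()' map --peptides db/peptides.fasta \
    --proteins fx/proteins.fasta --out hits.tsv
Rscript -e 'splicepep::splicepep_cli()' decoy --in fx/proteins.fasta --out decoy.fasta
Rscript -e 'splicepep::splicepep_cli()' fdr --hits hits.tsv --level peptide
```

Presets nest: `PEPPI_KB` (annotated regions, wild type) ⊆
`PEPPI_without_SNP` (all five types, wild type) ⊆ `PEPPI_with_SNP`
(all types plus SNP variants).

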