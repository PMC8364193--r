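# markerscreen

Marker-gene screening and quantification in shotgun metagenomes and
metatranscriptomes.

## The problem

Some of the most clinically interesting gut bacterial pathways are carried
by very few community members. The anaerobic γ-butyrobetaine (γbb)
pathway — whose *bbuA* gene marks bacteria that turn the carnitine
derivative γbb into disease-associated trimethylamine (TMA) — is present
at roughly one gene per thousand microbial genomes in stool metagenomes.
At that abundance, naive homology search is dominated by reads from
*near-neighbour* proteins (50–70% amino-acid identity to the marker) that
do different chemistry, and raw read counts are incomparable across
samples with different sequencing depth and community composition.

`markerscreen` is for microbiome researchers who want to survey such a
marker family across cohorts. It provides:

* **marker/decoy database construction** — candidate homolog pools are
  screened with a strict >70% global-identity homolog cutoff, clustered
  greedily at 50% identity, and every sequence between 50% and 70%
  identity to a marker is kept as a *decoy* to absorb misleading reads;
* **competitive translated-read classification** — each read is aligned in
  all six frames (Smith–Waterman, BLOSUM62, gap 11/1, k-mer seeded)
  against markers and decoys; a read is positive iff its best marker
  identity exceeds 70% and is ≥ its best decoy identity, with hits
  filtered at E < 10⁻⁴ and identity > 50%;
* **abundance in genes per microbial genome** —

      RPKM = (positive reads / total reads) × 10⁶ / gene length[kb]
      Abundance = RPKM × AGS × 10⁻⁹

  where AGS is the sample's average genome size (bp), so that one
  single-copy gene in every genome reads exactly 1.0;
* **cohort statistics** — prevalence fractions, gene/transcript
  concordance, and Mann–Whitney U association of gene presence with
  metabolite levels (exact enumeration for small tie-free samples, normal
  approximation with tie correction otherwise);
* **a synthetic community/cohort simulator** with full ground truth, so
  the whole pipeline is testable end to end without downloads.

## Worked example

Simulate a small community in which 20% of genomes carry the marker and
every genome carries a 50–65%-identity decoy homolog, then screen and
quantify:

```r
library(markerscreen)

spec <- community_spec(
  n_genomes = 50, genome_length_bp = 8000,
  marker_protein = random_protein(300, seed = 11),
  marker_carriage_rate = 0.2,
  n_decoy_genes_per_genome = 1, n_decoy_variants = 2,
  n_reads = 20000, seed = 3)
comm <- simulate_community(spec)

db <- build_marker_db(
  seq_tbl("marker1", spec$marker_protein, "protein"),
  comm$decoy_proteins)

reads <- simulate_reads(comm)
scr   <- screen_sample(reads, db, sample_id = "s1")
quantify_sample(scr, ags_bp = spec$genome_length_bp, db = db)
#> # A tibble: 1 × 8
#>   sample_id total_reads positive_reads gene_length_kb ags_bp  rpkm abundance present
#>   <chr>           <int>          <int>          <dbl>  <dbl> <dbl>     <dbl> <lgl>
#> 1 s1              20000            168          0.903   8000 9302.    0.0744 TRUE
```

Of the 20,000 reads, 168 are classified positive: every one of them truly
originates from a planted marker gene (decoy- and background-origin reads
are all rejected by the competitive rule), and the estimated abundance of
0.074 genes/genome tracks the planted truth of 0.06 (3 carrier genomes
among 50; the small excess is read-overlap bias at the gene ends plus
Poisson noise). Cohort tables built from such per-sample results feed
`prevalence()`, `associate_presence_with_metabolite()` and
`gene_transcript_concordance()`, with `autoplot()`/`plot_*()` figures.

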