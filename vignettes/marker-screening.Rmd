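---
title: "Screening gut metagenomes for marker genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening gut metagenomes for marker genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Low-abundance metabolic pathways of the gut microbiota — such as anaerobic
γ-butyrobetaine (γbb) reduction to trimethylamine, marked by the *bbuA*
gene — are carried by roughly one genome in a thousand. Detecting and
quantifying such a marker in shotgun metagenomes is dominated by two error
sources: reads from *near-neighbour homologs* (proteins 50–70% identical
to the marker that perform other chemistry) and the arbitrariness of
read-depth units. `markerscreen` implements a screening pipeline that
addresses both: a competitive negative-control (decoy) database absorbs
homolog reads, and RPKM × average-genome-size (AGS) normalisation converts
counts to *marker genes per microbial genome*, a unit comparable across
samples and cohorts.

## The screening model

**Databases.** The marker database holds the marker protein family. The
decoy database is built in three steps from a candidate pool of related
proteins: (1) any pool sequence whose global amino-acid identity to a
marker strictly exceeds the homolog cutoff (default 70%) is excluded — it
*is* the marker family; (2) the remainder is clustered greedily at 50%
identity and the representatives kept; (3) every pool sequence between 50%
and 70% identity to a marker is added back. Step 3 guarantees that the
nearest non-marker neighbours — the sequences most likely to shed
misleading reads — are always present to compete. Membership in the band
is judged by default against the maximum over all markers; a
`single_reference` option restricts it to one designated marker.

**Read classification.** Each read is translated in all six frames;
peptide segments are delimited by stop codons and alignments never cross a
stop. Segments are searched against both databases by Smith–Waterman local
alignment (BLOSUM62, gap open 11, gap extend 1, a gap of length *L*
costing 11 + *L*). Hits must satisfy E < 10⁻⁴ and identity > 50%, where
identity is computed over alignment columns with gap columns counting as
mismatches. The best hit per database is the highest-identity hit, ties
broken by raw score and then by subject id. A read is **positive** when
its best marker identity strictly exceeds 70% *and* is greater than or
equal to its best decoy identity — ties go to the marker. Each read is one
observation regardless of how many markers it hits; mates of a pair are
treated as independent reads. Metatranscriptome reads are classified by
the identical procedure; only the interpretation (transcript presence)
differs.

**Quantification.** Per sample,

$$\mathrm{RPKM} = \frac{\text{positive reads}/\text{total reads} \times 10^6}
{\text{gene length [kb]}}, \qquad
\mathrm{Abundance} = \mathrm{RPKM} \times \mathrm{AGS} \times 10^{-9},$$

with AGS the sample's average genome size in bp (an input, typically from
an external estimator). On a one-genome community carrying one single-copy
marker this chain returns exactly 1 gene/genome, which fixes the units and
is asserted in the tests. Presence defaults to ≥ 1 positive read; the
threshold is exposed. With several markers, the gene length defaults to
the length-weighted mean marker coding length — a single database-level
effective length, not the per-read best hit — since a sample-level
normaliser should not depend on which marker each read happened to hit.

**Cohort statistics.** Prevalence is the fraction of positive samples per
group. Metabolite associations compare levels between marker-positive and
-negative samples with the two-sided Mann–Whitney U test: the exact null
distribution (two-sided p doubling the smaller tail, capped at 1) when
n₁ + n₂ ≤ 12 without ties, otherwise the normal approximation with tie and
continuity corrections. Missing metabolite values are dropped pairwise.
Gene/transcript concordance reports the two conditional fractions of
transcript-positive samples among gene-positive and gene-negative samples;
the latter captures samples whose gene abundance sits below metagenomic
detection while the transcript is expressed.

## Numerical choices

* **E-values.** The in-house aligner computes Karlin–Altschul E-values,
  E = K·m·n·e^(−λS), with the published gapped-BLOSUM62 constants
  K = 0.041, λ = 0.267 as defaults; m is the query segment length. For
  read classification, **n is the combined marker-plus-decoy database
  length for both searches**. With per-database lengths, a read covering a
  conserved tail shared by marker and decoy can produce two identical
  perfect hits of which only the decoy's is filtered (its database being
  larger), defeating the competitive comparison precisely at the cutoff
  boundary; the symmetric convention removes this artifact.
* **Seeding.** A full alignment is attempted only after an exact
  amino-acid 5-mer match between a read segment and a database sequence
  (`seed_k`, configurable; 0 disables seeding). The subject is then
  examined on a window spanning the seed positions padded by the segment
  length plus a 25-residue gap allowance, so the windowed score equals the
  full-subject optimum whenever the optimal alignment involves a seeded
  region. Seeding can only miss hits that contain no exact 5-mer — far
  below the 70% positive cutoff for read-length queries — and the tests
  assert that positive calls agree with the seedless search.
* **Identity conventions.** Per-hit identity (local, over alignment
  columns) is used for classification; full-protein comparisons (homolog
  cutoffs, clustering, decoy band) use global Needleman–Wunsch identity
  with the same scoring. Published pairwise identities between named
  full-length proteins are reproduced by the global convention, which is
  therefore the documented default for such comparisons.
* **Determinism.** Greedy clustering processes sequences longest-first
  with lexical tie-breaks; classification tie-breaks are by raw score then
  subject id; all simulation randomness derives from a single spec seed,
  and identical spec + seed reproduces byte-identical FASTQ.
* **Degenerate inputs.** Reads shorter than 3 × `seed_k` nucleotides are
  flagged `too_short` and classified negative rather than erroring; a
  zero-read sample screens to zero counts with a warning and RPKM is an
  explicit error at zero total reads; an empty decoy pool degrades
  classification to the identity cutoff alone, with a warning.

## What the simulator emulates — and what it does not

`simulate_community()` plants marker and decoy coding sequences into
random sense-codon background genomes; `simulate_reads()` draws
length-proportional substitution-error short reads with uniform strand;
`simulate_cohort()` pairs metagenomes with transcriptomes in which marker
regions are re-weighted by an expression multiplier, and draws
log-normal γbb levels whose log-scale location is shifted down by the
effect size (in SD units) in truly marker-positive samples. The defaults
are the survey conditions the pipeline is validated under: 5,000 genomes
of 50 kb, a 400-residue (1.2-kb) marker at 10⁻³ genes/genome, one decoy
homolog gene per genome drawn from four variants mutated into a 50–65%
identity band, and 2 × 10⁶ reads of 150 nt at 0.5% substitution error.
Decoy genes are shared across genomes from a small set of variants — as a
real near-neighbour homolog is shared across taxa — and the same variant
proteins are handed to the database builder as the candidate pool,
mirroring how the real negative-control set contains homologs that exist
in nature.

Deliberate simplifications: background DNA is random codons rather than
real genes (a conservative, low-homology background — real backgrounds
contain distant homologs that the decoy band is designed to absorb);
errors are substitutions only, so translated frames stay intact and indel
robustness is untested; there is no taxon abundance distribution (each
genome is equally weighted) and no platform-specific error or quality
model. Passing tests therefore demonstrate the *logic* of the screening
procedure — specificity against 50–65% homologs, abundance recovery,
calibration of the statistics — not performance on real sequencer output.

* `mutate_to_identity()` substitutes residues (no indels) until the
  variant's global identity lands within ±2 points of the target, erroring
  after bounded attempts for unreachable targets (very low identity on
  short proteins).

## Problem sizes used in validation

The end-to-end abundance-recovery check runs five independent communities
at the full survey conditions above (10⁷ reads in total) and requires the
mean estimated abundance within ±50% of 10⁻³ genes/genome; a single
community completes in under two minutes on one CPU thanks to k-mer
seeding. Estimates carry a small (< 10%) upward bias because reads
overlapping a gene end by at least a dozen codons are detectable, which
slightly enlarges the effective target relative to the gene length used in
RPKM; this is inherent to read-overlap counting and well inside the
tolerance. Depth invariance, specificity (10⁵ reads of a marker-free,
decoy-bearing community), statistical calibration (1,000 replicates at
n = 30 + 30) and determinism are exercised at reduced sizes chosen so the
binomial/Poisson error of each check is small relative to its assertion.

## Known limitations

* Cohort-level figures observed in real human populations (prevalences of
  15–85% across cohorts, transcript positivity of 27–56%) depend on
  external cohort data and are not reproduced here; property-based checks
  on synthetic cohorts stand in for them.
* A read is one observation: a read with several qualifying alignments
  (to multiple markers, or several high-scoring pairs against one marker)
  is counted once, as a positive read, never per alignment.
* RPKM follows the standard reads-per-kilobase-per-million definition;
  this is the only reading dimensionally consistent with a
  genes-per-genome abundance on the 10⁻³ scale.
* Average genome size estimation is out of scope; AGS is an input in bp.
* No multiple-testing correction is applied to cohort comparisons; users
  comparing many metabolites should adjust externally.
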