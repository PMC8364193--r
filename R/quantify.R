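# Positive-read tallies -> RPKM -> genes per microbial genome.
# Abundance = RPKM x AGS x 1e-9, where AGS is the sample's average genome
# size in bp (an input, typically estimated by a tool such as
# MicrobeCensus). On a one-genome community carrying one single-copy
# marker this chain returns exactly 1 gene/genome, which fixes the units.

#' Reads per kilobase per million sample reads
#'
#' `rpkm = (positive_reads / total_reads) * 1e6 / gene_length_kb`, exactly
#' linear in `positive_reads` and inversely proportional to sequencing
#' depth.
#'
#' @param positive_reads,total_reads read counts (vectorised);
#'   `total_reads >= 1`.
#' @param gene_length_kb marker gene length in kilobases (> 0).
#' @return numeric RPKM.
#' @export
#' @examples
#' rpkm(10, 1e6, 1.0) # 10
rpkm <- function(positive_reads, total_reads, gene_length_kb) {
  if (any(total_reads < 1)) {
    abort("RPKM is undefined for a sample with zero total reads")
  }
  stopifnot(all(gene_length_kb > 0), all(positive_reads >= 0),
            all(positive_reads <= total_reads))
  (positive_reads / total_reads) * 1e6 / gene_length_kb
}

#' Marker genes per microbial genome
#'
#' `abundance = rpkm * ags_bp * 1e-9`.
#'
#' @param rpkm RPKM value(s).
#' @param ags_bp average genome size in base pairs (> 0).
#' @return numeric genes-per-genome abundance.
#' @export
#' @examples
#' abundance(10, 5e6) # 0.05
abundance <- function(rpkm, ags_bp) {
  stopifnot(all(ags_bp > 0), all(rpkm >= 0))
  rpkm * ags_bp * 1e-9
}

#' Effective marker gene length of a database
#'
#' Length-weighted mean marker coding length, in kb. Protein lengths are
#' converted to coding-sequence lengths as `3 * (aa + 1)` nt (one stop
#' codon).
#'
#' @param db a [build_marker_db()] object.
#' @return effective gene length in kb.
#' @export
effective_gene_length_kb <- function(db) {
  nt <- 3 * (nchar(db$markers$seq) + 1)
  sum(nt * nt) / sum(nt) / 1000
}

#' Quantify one screened sample
#'
#' Assembles RPKM, AGS-normalised abundance and the presence call for a
#' sample screened with [screen_sample()]. Presence defaults to at least
#' one positive read (`presence_min_reads = 1`).
#'
#' @param screen one-row tibble from [screen_sample()] (or several rows;
#'   all are quantified).
#' @param ags_bp average genome size per sample, in bp (scalar or vector
#'   matching rows of `screen`).
#' @param gene_length_kb marker gene length in kb; when `NULL`, derived
#'   from `db` via [effective_gene_length_kb()].
#' @param db marker database used for the default gene length.
#' @param presence_min_reads minimum positive reads for `present = TRUE`.
#' @return tibble with columns `sample_id`, `total_reads`,
#'   `positive_reads`, `gene_length_kb`, `ags_bp`, `rpkm`, `abundance`,
#'   `present`.
#' @export
quantify_sample <- function(screen, ags_bp, gene_length_kb = NULL, db = NULL,
                            presence_min_reads = 1L) {
  if (is.null(gene_length_kb)) {
    if (is.null(db)) abort("supply either gene_length_kb or db")
    gene_length_kb <- effective_gene_length_kb(db)
  }
  if (any(screen$total_reads < 1)) {
    abort("RPKM is undefined for a sample with zero total reads")
  }
  r <- rpkm(screen$positive_reads, screen$total_reads, gene_length_kb)
  tibble(sample_id = screen$sample_id,
         total_reads = screen$total_reads,
         positive_reads = screen$positive_reads,
         gene_length_kb = gene_length_kb,
         ags_bp = ags_bp,
         rpkm = r,
         abundance = abundance(r, ags_bp),
         present = screen$positive_reads >= presence_min_reads)
}
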