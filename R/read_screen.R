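# Competitive translated-read classification. Every read is searched in
# all six reading frames against the marker and decoy databases; a read is
# positive when its best marker hit clears the identity cutoff and is at
# least as good (by identity) as its best decoy hit.

#' Search parameter set
#'
#' @param evalue_cutoff hits must have E-value strictly below this
#'   (default 1e-4).
#' @param report_identity_floor_pct hits must have identity strictly above
#'   this to be reported at all (default 50).
#' @param positive_identity_cutoff_pct a read is positive only if its best
#'   marker identity strictly exceeds this (default 70).
#' @param matrix_name,gap_open,gap_extend scoring scheme (see
#'   [local_align()]).
#' @param seed_k exact amino-acid k-mer length required to trigger a full
#'   local alignment (default 5; `0` disables seeding and aligns every
#'   read segment against every database sequence).
#' @param K,lam Karlin-Altschul constants for E-values.
#' @return list of class `search_params`.
#' @export
search_params <- function(evalue_cutoff = 1e-4,
                          report_identity_floor_pct = 50,
                          positive_identity_cutoff_pct = 70,
                          matrix_name = "BLOSUM62",
                          gap_open = 11, gap_extend = 1,
                          seed_k = 5, K = 0.041, lam = 0.267) {
  stopifnot(evalue_cutoff > 0,
            report_identity_floor_pct > 0,
            report_identity_floor_pct <= positive_identity_cutoff_pct,
            positive_identity_cutoff_pct <= 100,
            gap_open >= gap_extend, gap_extend >= 0,
            seed_k >= 0, seed_k <= 5, K > 0, lam > 0)
  structure(list(evalue_cutoff = evalue_cutoff,
                 report_identity_floor_pct = report_identity_floor_pct,
                 positive_identity_cutoff_pct = positive_identity_cutoff_pct,
                 matrix_name = matrix_name, gap_open = gap_open,
                 gap_extend = gap_extend, seed_k = seed_k, K = K, lam = lam),
            class = "search_params")
}

#' Classify reads against a marker/decoy database
#'
#' Each read is translated in six frames (stop-codon-delimited peptide
#' segments; alignments never cross a stop), seeded by exact amino-acid
#' k-mers, and locally aligned against both databases. Hits are filtered
#' to `evalue < evalue_cutoff` and `identity > report_identity_floor_pct`.
#' E-values are computed against the combined marker-plus-decoy database
#' length for both searches, so that competing hits of equal score face
#' the same cutoff regardless of the relative database sizes;
#' the best hit per database is the highest-identity one (ties broken by
#' higher raw score, then lexically smaller subject id). A read is
#' positive iff its best marker identity strictly exceeds
#' `positive_identity_cutoff_pct` and is greater than or equal to its best
#' decoy identity (ties go to the marker). Reads shorter than
#' `3 * seed_k` nucleotides are flagged `too_short` and classified
#' negative rather than raising an error.
#'
#' @param reads sequence table of nucleotide reads (`id`, `seq`).
#' @param db a [build_marker_db()] object (an empty decoy set is allowed:
#'   classification then degenerates to the identity cutoff alone).
#' @param params a [search_params()] object.
#' @return tibble, one row per read: best marker / decoy hit details
#'   (id, identity, raw score, E-value, frame) and the `positive` flag.
#' @export
classify_reads <- function(reads, db, params = search_params()) {
  stopifnot(inherits(db, "marker_db"), inherits(params, "search_params"))
  if (nrow(reads) == 0) {
    return(tibble(read_id = character(), too_short = logical(),
                  marker_id = character(), marker_identity = numeric(),
                  marker_score = integer(), marker_evalue = numeric(),
                  marker_frame = integer(), decoy_id = character(),
                  decoy_identity = numeric(), decoy_score = integer(),
                  decoy_evalue = numeric(), decoy_frame = integer(),
                  positive = logical()))
  }
  mat <- substitution_matrix(params$matrix_name)
  res <- cpp_classify_reads(
    toupper(reads$seq), reads$id,
    db$markers$seq, db$markers$id,
    db$decoys$seq, db$decoys$id,
    mat, paste(rownames(mat), collapse = ""),
    params$gap_open, params$gap_extend, params$seed_k,
    params$K, params$lam, params$evalue_cutoff,
    params$report_identity_floor_pct, params$positive_identity_cutoff_pct)
  as_tibble(res)
}

#' Classify a single read
#'
#' @param read a single nucleotide sequence (character scalar).
#' @inheritParams classify_reads
#' @param read_id identifier recorded in the result.
#' @return one-row tibble as in [classify_reads()].
#' @export
classify_read <- function(read, db, params = search_params(),
                          read_id = "read") {
  classify_reads(tibble(id = read_id, seq = read), db, params)
}

#' Screen one sample of reads
#'
#' Tallies total and positive reads; each read is one observation and is
#' counted at most once however many markers it hits. Positive-read
#' classifications are kept in the `positives` list-column.
#'
#' @inheritParams classify_reads
#' @param sample_id sample identifier.
#' @return one-row tibble: `sample_id`, `total_reads`, `positive_reads`
#'   and a list-column `positives` holding the per-positive-read
#'   classification tibble.
#' @export
screen_sample <- function(reads, db, params = search_params(),
                          sample_id = "sample") {
  if (nrow(reads) == 0) {
    warn(sprintf("sample '%s' has zero reads; downstream RPKM is undefined",
                 sample_id))
    cls <- classify_reads(reads, db, params)
    return(tibble(sample_id = sample_id, total_reads = 0L,
                  positive_reads = 0L, positives = list(cls)))
  }
  cls <- classify_reads(reads, db, params)
  tibble(sample_id = sample_id,
         total_reads = nrow(reads),
         positive_reads = sum(cls$positive),
         positives = list(cls[cls$positive, , drop = FALSE]))
}

#' Screen contigs or genomes for marker homologs
#'
#' Protein queries are aligned against all six translated frames of each
#' contig (stop-codon-delimited segments, as in a tblastn search). Hits
#' passing the E-value cutoff are reported with their nucleotide spans
#' mapped back from peptide coordinates (0-based half-open, plus a 1-based
#' inclusive `start1` display column); `is_homolog` marks hits whose
#' identity strictly exceeds `homolog_cutoff`, and `at_contig_end` flags
#' spans that begin or end within one codon of a contig boundary
#' (candidate truncated genes).
#'
#' @param contigs sequence table of nucleotide contigs.
#' @param queries sequence table of protein queries.
#' @param params a [search_params()] object (its reporting floor is not
#'   applied here; all positive-scoring hits below the E-value cutoff are
#'   returned).
#' @param homolog_cutoff identity threshold for the `is_homolog` call.
#' @return tibble of genomic hits.
#' @export
screen_contigs <- function(contigs, queries, params = search_params(),
                           homolog_cutoff = 70) {
  stopifnot(inherits(params, "search_params"))
  validate_seq_tbl(queries, "protein")
  mat <- substitution_matrix(params$matrix_name)
  res <- cpp_screen_contigs(
    toupper(contigs$seq), contigs$id, queries$seq, queries$id,
    mat, paste(rownames(mat), collapse = ""),
    params$gap_open, params$gap_extend, params$seed_k,
    params$K, params$lam, params$evalue_cutoff, 0)
  out <- as_tibble(res)
  out$is_homolog <- out$identity_pct > homolog_cutoff
  out$start1 <- out$nt_start + 1L   # 1-based inclusive, for human-readable reports
  out
}

#' Genomic context of marker homolog hits
#'
#' For each hit, lists annotated genes on the same contig whose span lies
#' within `window_bp` of the hit span, with strand and signed offset
#' (gene start minus hit start), sorted by offset, and carries the hit's
#' contig-end truncation flag.
#'
#' @param hits tibble from [screen_contigs()] (typically filtered to
#'   `is_homolog`).
#' @param annotations tibble with columns `contig_id`, `gene_id`, `start`,
#'   `end` (0-based half-open) and `strand`. Annotations naming a contig
#'   not present among the hits raise an error.
#' @param window_bp neighbourhood half-width in bp (default 10000).
#' @return tibble with one row per (hit, neighbouring gene).
#' @export
detect_cluster_context <- function(hits, annotations, window_bp = 10000) {
  stopifnot(all(c("contig_id", "gene_id", "start", "end", "strand") %in%
                  names(annotations)))
  unknown <- setdiff(unique(annotations$contig_id), unique(hits$contig_id))
  if (length(unknown) > 0) {
    abort(sprintf("annotations name unknown contig id(s): %s",
                  paste(utils::head(unknown, 3), collapse = ", ")))
  }
  if (nrow(hits) == 0) return(tibble())
  hits$hit_row <- seq_len(nrow(hits))
  joined <- dplyr::inner_join(
    hits[, c("hit_row", "contig_id", "query_id", "nt_start", "nt_end",
             "at_contig_end")],
    annotations, by = "contig_id", relationship = "many-to-many")
  joined |>
    dplyr::filter(.data$end > .data$nt_start - window_bp,
                  .data$start < .data$nt_end + window_bp) |>
    dplyr::mutate(offset = .data$start - .data$nt_start) |>
    dplyr::arrange(.data$hit_row, .data$offset) |>
    dplyr::select("hit_row", "contig_id", "query_id",
                  hit_start = "nt_start", hit_end = "nt_end",
                  "at_contig_end", "gene_id",
                  gene_start = "start", gene_end = "end",
                  gene_strand = "strand", "offset")
}

#' Write genomic hits as BED
#'
#' Six-column BED (0-based half-open, score = rounded identity) via
#' rtracklayer when available.
#'
#' @param hits tibble from [screen_contigs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path) {
  if (!requireNamespace("GenomicRanges", quietly = TRUE) ||
      !requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("BED export requires the GenomicRanges and rtracklayer packages")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = hits$contig_id,
    ranges = IRanges::IRanges(start = hits$nt_start + 1L, end = hits$nt_end),
    strand = ifelse(hits$frame > 0, "+", "-"))
  gr$name <- hits$query_id
  gr$score <- round(hits$identity_pct)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
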