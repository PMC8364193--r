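# File-in / file-out orchestration of the three pipeline stages:
# database construction, per-sample screening + quantification, and
# cohort statistics. Each stage writes a manifest of its parameters so a
# run can be reproduced from its output directory alone.

write_tsv_plain <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  as_tibble(read.table(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE))
}

write_run_manifest <- function(out_dir, stage, params) {
  flat <- purrr::imap_chr(params, function(v, k) {
    paste(k, paste(format(v), collapse = ","), sep = "\t")
  })
  writeLines(c(sprintf("stage\t%s", stage), flat),
             file.path(out_dir, sprintf("%s_manifest.tsv", stage)))
}

#' Build a marker/decoy database from FASTA inputs
#'
#' Reads marker and candidate-pool FASTA files, runs
#' [build_marker_db()], and writes the decoy FASTA, the cluster
#' membership TSV and the per-sequence role manifest to `out_dir`.
#' Deterministic: rerunning on the same inputs reproduces the same
#' manifest.
#'
#' @param markers_fasta path to the marker protein FASTA.
#' @param pool_fasta path to the candidate decoy pool FASTA (optional;
#'   omitting it yields an empty decoy set with a warning).
#' @param out_dir output directory (created if needed).
#' @inheritParams build_marker_db
#' @return the `marker_db`, invisibly.
#' @export
run_build_db <- function(markers_fasta, pool_fasta = NULL, out_dir,
                         homolog_cutoff = 70, band_lo = 50,
                         cluster_threshold = 50, single_reference = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  markers <- read_fasta(markers_fasta)
  pool <- if (is.null(pool_fasta)) markers[0, ] else read_fasta(pool_fasta)
  db <- build_marker_db(markers, pool, homolog_cutoff = homolog_cutoff,
                        band_lo = band_lo,
                        cluster_threshold = cluster_threshold,
                        single_reference = single_reference)
  write_tsv_plain(db$manifest, file.path(out_dir, "db_manifest.tsv"))
  if (nrow(db$decoys) > 0) {
    write_fasta(db$decoys, file.path(out_dir, "decoys.fasta"))
  }
  if (!is.null(db$clusters)) {
    write_tsv_plain(db$clusters$membership[, c("id", "representative")],
                    file.path(out_dir, "cluster_membership.tsv"))
  }
  write_run_manifest(out_dir, "build_db", list(
    markers_fasta = markers_fasta, pool_fasta = pool_fasta %||% "",
    homolog_cutoff = homolog_cutoff, band_lo = band_lo,
    cluster_threshold = cluster_threshold,
    n_markers = nrow(db$markers), n_decoys = nrow(db$decoys)))
  invisible(db)
}

#' Screen and quantify a set of samples
#'
#' For each row of `samples` (columns `sample_id`, `reads_path`, optional
#' `ags_bp`), reads the FASTQ/FASTA file, classifies reads against the
#' database, and quantifies. Samples whose per-sample classification
#' output already exists in `out_dir` are resumed (skipped). A sample
#' without an AGS value gets RPKM and presence but a blank abundance,
#' with a warning.
#'
#' @param samples tibble describing the samples.
#' @param db a `marker_db`.
#' @param out_dir output directory.
#' @param params a [search_params()].
#' @param gene_length_kb marker gene length (default: database effective
#'   length).
#' @param presence_min_reads presence threshold in positive reads.
#' @return quantification tibble (also written to
#'   `out_dir/quantification.tsv`).
#' @export
run_screen <- function(samples, db, out_dir, params = search_params(),
                       gene_length_kb = NULL, presence_min_reads = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gene_length_kb <- gene_length_kb %||% effective_gene_length_kb(db)
  if (nrow(samples) == 0) {
    out <- tibble(sample_id = character(), total_reads = integer(),
                  positive_reads = integer(), gene_length_kb = numeric(),
                  ags_bp = numeric(), rpkm = numeric(), abundance = numeric(),
                  present = logical())
    write_tsv_plain(out, file.path(out_dir, "quantification.tsv"))
    return(out)
  }
  rows <- purrr::pmap(samples, function(sample_id, reads_path, ...) {
    extra <- list(...)
    cls_path <- file.path(out_dir, sprintf("%s_positives.tsv", sample_id))
    count_path <- file.path(out_dir, sprintf("%s_counts.tsv", sample_id))
    if (file.exists(cls_path) && file.exists(count_path)) {
      counts <- read_tsv_plain(count_path)
      scr <- tibble(sample_id = sample_id,
                    total_reads = counts$total_reads,
                    positive_reads = counts$positive_reads)
    } else {
      reads <- if (grepl("\\.(fastq|fq)$", reads_path)) read_fastq(reads_path)
               else read_fasta(reads_path)
      scr <- screen_sample(reads, db, params, sample_id = sample_id)
      write_tsv_plain(scr$positives[[1]], cls_path)
      write_tsv_plain(scr[, c("sample_id", "total_reads", "positive_reads")],
                      count_path)
      scr <- scr[, c("sample_id", "total_reads", "positive_reads")]
    }
    ags <- extra$ags_bp
    if (is.null(ags) || is.na(ags)) {
      warn(sprintf("sample '%s' has no AGS value; abundance left blank",
                   sample_id))
      q <- quantify_sample(scr, ags_bp = 1, gene_length_kb = gene_length_kb,
                           presence_min_reads = presence_min_reads)
      q$ags_bp <- NA_real_
      q$abundance <- NA_real_
      q
    } else {
      quantify_sample(scr, ags_bp = ags, gene_length_kb = gene_length_kb,
                      presence_min_reads = presence_min_reads)
    }
  })
  out <- dplyr::bind_rows(rows)
  write_tsv_plain(out, file.path(out_dir, "quantification.tsv"))
  write_run_manifest(out_dir, "screen", list(
    evalue_cutoff = params$evalue_cutoff,
    report_identity_floor_pct = params$report_identity_floor_pct,
    positive_identity_cutoff_pct = params$positive_identity_cutoff_pct,
    seed_k = params$seed_k, gene_length_kb = gene_length_kb,
    n_samples = nrow(samples)))
  out
}

#' Cohort statistics report
#'
#' From a cohort table (one row per sample with presence flags, optional
#' transcript presence, abundance and metabolite columns), writes
#' prevalence, metabolite-association and gene/transcript-concordance
#' tables.
#'
#' @param table cohort tibble (or path to a TSV).
#' @param out_dir output directory.
#' @param metabolite name of the metabolite column to associate with gene
#'   presence (default `"gbb"`; skipped with a warning when absent).
#' @param by name of the grouping column for prevalence (optional).
#' @return named list of result tibbles, invisibly.
#' @export
run_stats <- function(table, out_dir, metabolite = "gbb", by = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(table)) table <- read_tsv_plain(table)
  res <- list()
  res$prevalence <- if (is.null(by)) prevalence(table)
                    else prevalence(table, by = !!rlang::sym(by))
  write_tsv_plain(res$prevalence, file.path(out_dir, "prevalence.tsv"))
  if (metabolite %in% names(table)) {
    res$association <- associate_presence_with_metabolite(
      table, metabolite = !!rlang::sym(metabolite))
    write_tsv_plain(res$association, file.path(out_dir, "association.tsv"))
  } else {
    warn(sprintf("metabolite column '%s' not found; association skipped",
                 metabolite))
  }
  if ("transcript_present" %in% names(table) &&
      any(!is.na(table$transcript_present))) {
    res$concordance <- gene_transcript_concordance(table)
    write_tsv_plain(res$concordance, file.path(out_dir, "concordance.tsv"))
  }
  invisible(res)
}
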