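# Marker / negative-control database construction. The decoy set absorbs
# reads from near-neighbour homologs (50-70% identity to a marker) under
# the competitive best-hit rule, so that only reads closer to a true
# marker than to any decoy are counted.

#' Greedy incremental clustering by global identity
#'
#' Sequences are processed longest-first (ties broken lexicographically by
#' id); each joins the first existing representative to which its global
#' identity is at least `threshold_pct`, otherwise it founds a new
#' cluster. Deterministic given the input set.
#'
#' @param seqs sequence table (`id`, `seq`; protein).
#' @param threshold_pct clustering identity threshold in (0, 100].
#' @inheritParams local_align
#' @return object of class `identity_clusters`: list with `membership`
#'   (tibble: id, representative, identity_to_rep), `representatives`
#'   (character) and `threshold`.
#' @export
cluster_by_identity <- function(seqs, threshold_pct, matrix_name = "BLOSUM62",
                                gap_open = 11, gap_extend = 1) {
  stopifnot(threshold_pct > 0, threshold_pct <= 100)
  if (nrow(seqs) == 0) abort("cannot cluster an empty sequence set")
  ord <- order(-nchar(seqs$seq), seqs$id)
  seqs <- seqs[ord, ]
  reps <- character(0)
  rep_seqs <- character(0)
  member_rep <- character(nrow(seqs))
  member_ident <- numeric(nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    assigned <- FALSE
    if (length(reps) > 0) {
      idents <- global_identity(seqs$seq[i], rep_seqs, matrix_name,
                                gap_open, gap_extend)
      hit <- which(idents >= threshold_pct)
      if (length(hit) > 0) {
        member_rep[i] <- reps[hit[1]]
        member_ident[i] <- idents[hit[1]]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      reps <- c(reps, seqs$id[i])
      rep_seqs <- c(rep_seqs, seqs$seq[i])
      member_rep[i] <- seqs$id[i]
      member_ident[i] <- 100
    }
  }
  structure(list(
    membership = tibble(id = seqs$id, representative = member_rep,
                        identity_to_rep = member_ident),
    representatives = reps,
    threshold = threshold_pct
  ), class = "identity_clusters")
}

#' @export
print.identity_clusters <- function(x, ...) {
  cat(sprintf("identity clusters: %d sequences in %d clusters at >= %g%% identity\n",
              nrow(x$membership), length(x$representatives), x$threshold))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
tidy.identity_clusters <- function(x, ...) x$membership

#' Maximum global identity of candidates to a marker set
#'
#' @param candidates character vector of protein sequences.
#' @param markers marker sequence table (`id`, `seq`).
#' @inheritParams local_align
#' @return numeric vector of max identities.
#' @export
max_identity_to_markers <- function(candidates, markers,
                                    matrix_name = "BLOSUM62",
                                    gap_open = 11, gap_extend = 1) {
  stopifnot(nrow(markers) > 0)
  vapply(candidates, function(cand) {
    max(global_identity(cand, markers$seq, matrix_name, gap_open, gap_extend))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Is a candidate protein a marker homolog?
#'
#' True iff the maximum global identity to any marker strictly exceeds
#' `cutoff_pct` (the ">70% amino acid sequence identity" homolog rule; a
#' candidate at exactly the cutoff is not a homolog).
#'
#' @param candidates character vector of protein sequences.
#' @param markers marker sequence table.
#' @param cutoff_pct homolog identity cutoff (percent, default 70).
#' @inheritParams local_align
#' @return logical vector.
#' @export
is_homolog <- function(candidates, markers, cutoff_pct = 70,
                       matrix_name = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  max_identity_to_markers(candidates, markers, matrix_name,
                          gap_open, gap_extend) > cutoff_pct
}

#' Build the marker plus negative-control (decoy) database
#'
#' Implements the three-step negative-control construction: (1) candidate
#' pool sequences that are themselves marker homologs (identity strictly
#' above `homolog_cutoff`) are excluded; (2) the remainder is clustered
#' greedily at `cluster_threshold` and the representatives kept; (3) every
#' remaining pool sequence whose maximum identity to a marker lies in
#' `(band_lo, homolog_cutoff]` is added. The decoy set is the union of (2)
#' and (3), de-duplicated by exact sequence (first id kept; duplicates are
#' flagged in the manifest).
#'
#' @param markers marker sequence table (`id`, `seq`; protein).
#' @param pool candidate decoy pool sequence table (may be empty).
#' @param homolog_cutoff homolog identity cutoff (percent; also the upper
#'   bound of the inclusion band).
#' @param band_lo lower bound (exclusive) of the identity inclusion band.
#' @param cluster_threshold greedy clustering threshold for step (2).
#' @param single_reference optional id of one marker; when given, band
#'   membership in step (3) is judged against that marker alone rather
#'   than the maximum over all markers.
#' @inheritParams local_align
#' @return object of class `marker_db`: list with `markers`, `decoys`
#'   (sequence tibbles), `manifest` (per-sequence role and max identity to
#'   marker), `clusters`, and the thresholds used.
#' @export
build_marker_db <- function(markers, pool,
                            homolog_cutoff = 70, band_lo = 50,
                            cluster_threshold = 50, single_reference = NULL,
                            matrix_name = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  validate_seq_tbl(markers, "protein")
  validate_seq_tbl(pool, "protein")
  stopifnot(nrow(markers) > 0, homolog_cutoff > 0, homolog_cutoff <= 100,
            band_lo < homolog_cutoff)

  band_ref <- if (is.null(single_reference)) markers else {
    ref <- markers[markers$id == single_reference, ]
    if (nrow(ref) == 0) abort("single_reference id not found among markers")
    ref
  }

  if (nrow(pool) == 0) {
    warn("empty candidate pool: decoy set is empty; classification degenerates to the identity cutoff alone")
    return(new_marker_db(markers, pool[0, ], NULL, tibble(
      id = markers$id, role = "marker", max_identity_to_marker = 100,
      duplicate_of = NA_character_), homolog_cutoff, band_lo, cluster_threshold))
  }

  max_ident <- max_identity_to_markers(pool$seq, markers, matrix_name,
                                       gap_open, gap_extend)
  band_ident <- if (is.null(single_reference)) max_ident else
    max_identity_to_markers(pool$seq, band_ref, matrix_name, gap_open, gap_extend)

  keep <- max_ident <= homolog_cutoff   # step 1: exclude homologs (> cutoff)
  pool_kept <- pool[keep, , drop = FALSE]
  if (nrow(pool_kept) == 0) {
    warn("candidate pool empty after homolog exclusion: decoy set is empty")
    manifest <- tibble(
      id = c(markers$id, pool$id),
      role = c(rep("marker", nrow(markers)), rep("excluded_homolog", nrow(pool))),
      max_identity_to_marker = c(rep(100, nrow(markers)), max_ident),
      duplicate_of = NA_character_)
    return(new_marker_db(markers, pool[0, ], NULL, manifest,
                         homolog_cutoff, band_lo, cluster_threshold))
  }

  clusters <- cluster_by_identity(pool_kept, cluster_threshold,
                                  matrix_name, gap_open, gap_extend)
  rep_ids <- clusters$representatives                        # step 2
  band_ids <- pool_kept$id[band_ident[keep] > band_lo]       # step 3
  decoy_ids <- union(rep_ids, band_ids)
  decoys <- pool_kept[match(decoy_ids, pool_kept$id), , drop = FALSE]

  # de-duplicate by exact sequence; keep the first id, flag the rest
  dup <- duplicated(decoys$seq)
  dup_of <- rep(NA_character_, nrow(decoys))
  if (any(dup)) {
    first_id <- decoys$id[match(decoys$seq, decoys$seq)]
    dup_of[dup] <- first_id[dup]
  }
  decoy_final <- decoys[!dup, , drop = FALSE]

  if (any(decoy_final$id %in% markers$id)) {
    abort("marker and decoy id sets must be disjoint")
  }

  pool_roles <- dplyr::case_when(
    !keep ~ "excluded_homolog",
    pool$id %in% decoys$id[dup] ~ "decoy_duplicate",
    pool$id %in% decoy_final$id ~ "decoy",
    TRUE ~ "clustered_member")
  manifest <- dplyr::bind_rows(
    tibble(id = markers$id, role = "marker", max_identity_to_marker = 100,
           duplicate_of = NA_character_),
    tibble(id = pool$id, role = pool_roles, max_identity_to_marker = max_ident,
           duplicate_of = dup_of[match(pool$id, decoys$id)]))

  new_marker_db(markers, decoy_final, clusters, manifest,
                homolog_cutoff, band_lo, cluster_threshold)
}

new_marker_db <- function(markers, decoys, clusters, manifest,
                          homolog_cutoff, band_lo, cluster_threshold) {
  structure(list(
    markers = markers, decoys = decoys, clusters = clusters,
    manifest = manifest, homolog_identity_cutoff = homolog_cutoff,
    band = c(band_lo, homolog_cutoff), cluster_threshold = cluster_threshold
  ), class = "marker_db")
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf(
    "marker_db: %d marker(s), %d decoy(s); homolog cutoff >%g%%, decoy band (%g, %g]\n",
    nrow(x$markers), nrow(x$decoys), x$homolog_identity_cutoff,
    x$band[1], x$band[2]))
  invisible(x)
}

#' @export
tidy.marker_db <- function(x, ...) x$manifest

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.marker_db <- function(x, ...) {
  tibble(n_markers = nrow(x$markers), n_decoys = nrow(x$decoys),
         homolog_identity_cutoff = x$homolog_identity_cutoff,
         band_lo = x$band[1], band_hi = x$band[2],
         cluster_threshold = x$cluster_threshold)
}
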