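# Independent oracles used across the suite. These deliberately avoid the
# package's C++ alignment path: scores come either from a plain-R dynamic
# program or from Biostrings::pairwiseAlignment.

# plain-R affine-gap Smith-Waterman score (no traceback); gap of length L
# costs open + L * ext
oracle_sw_score <- function(q, s, gap_open = 11, gap_ext = 1) {
  mat <- markerscreen::substitution_matrix("BLOSUM62")
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                              Ix[i, j + 1] - gap_ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                              Iy[i + 1, j] - gap_ext)
      sub <- mat[qc[i], sc[j]]
      M[i + 1, j + 1] <- max(0, sub + max(M[i, j], Ix[i, j], Iy[i, j]))
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Biostrings-based local hit: score + identity over alignment columns
oracle_local_hit <- function(q, s, gap_open = 11, gap_ext = 1) {
  mat <- markerscreen::substitution_matrix("BLOSUM62")
  pa <- Biostrings::pairwiseAlignment(q, s, substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_ext, type = "local")
  sc <- Biostrings::score(pa)
  if (sc <= 0) return(NULL)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  su <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  list(score = sc, identity = 100 * sum(p == su) / length(p))
}

# literal application of the read-positivity rule, seedless, via Biostrings.
# Returns the positive flag for one read against marker/decoy sequence sets.
oracle_classify_positive <- function(read, marker_seqs, decoy_seqs,
                                     evalue_cutoff = 1e-4, floor_pct = 50,
                                     pos_cutoff = 70, K = 0.041, lam = 0.267) {
  frames <- markerscreen::translate_six_frames(read)$peptide
  # combined database length for E-values, matching the symmetric
  # competitive-comparison convention
  n_db <- sum(nchar(marker_seqs)) + sum(nchar(decoy_seqs))
  best_for <- function(db_seqs) {
    if (length(db_seqs) == 0) return(NULL)
    best <- NULL
    for (aa in frames) {
      for (seg in strsplit(aa, "*", fixed = TRUE)[[1]]) {
        if (nchar(seg) < 1) next
        for (subj in db_seqs) {
          h <- oracle_local_hit(seg, subj)
          if (is.null(h)) next
          e <- K * nchar(seg) * n_db * exp(-lam * h$score)
          if (e >= evalue_cutoff || h$identity <= floor_pct) next
          if (is.null(best) || h$identity > best$identity ||
              (h$identity == best$identity && h$score > best$score)) {
            best <- h
          }
        }
      }
    }
    best
  }
  bm <- best_for(marker_seqs)
  bd <- best_for(decoy_seqs)
  !is.null(bm) && bm$identity > pos_cutoff &&
    (is.null(bd) || bm$identity >= bd$identity)
}

# exact two-sided Mann-Whitney p by complete enumeration of group
# assignments (doubling the smaller tail, capped at 1)
oracle_mwu_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_of <- function(sel) {
    r <- rank(pooled)
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(idx, 2, u_of)
  lower <- mean(us <= u_obs)
  upper <- mean(us >= u_obs)
  min(1, 2 * min(lower, upper))
}

# small deterministic toy protein set for database tests
toy_proteins <- function(seed = 42) {
  withr::with_seed(seed, {
    marker <- markerscreen::random_protein(120, seed = seed)
    list(
      marker = marker,
      near60 = markerscreen::mutate_to_identity(marker, 60, seed = seed + 1),
      near55 = markerscreen::mutate_to_identity(marker, 55, seed = seed + 2),
      far = markerscreen::random_protein(110, seed = seed + 3)
    )
  })
}

# build a marker_db directly from explicit marker / decoy sequences,
# bypassing construction (for crafting classification edge cases)
raw_db <- function(marker_seqs, decoy_seqs) {
  markerscreen:::new_marker_db(
    markers = tibble::tibble(id = names(marker_seqs), seq = unname(marker_seqs)),
    decoys = tibble::tibble(
      id = names(decoy_seqs) %||% character(0),
      seq = unname(decoy_seqs) %||% character(0)),
    clusters = NULL, manifest = tibble::tibble(),
    homolog_cutoff = 70, band_lo = 50, cluster_threshold = 50)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
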