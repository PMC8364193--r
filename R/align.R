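# Protein alignment substrate: Smith-Waterman / Needleman-Wunsch with
# affine gaps (a gap of length L costs gap_open + L * gap_extend, the
# convention of Biostrings::pairwiseAlignment) over a named substitution
# matrix. Percent identity is always computed over alignment columns, with
# gap columns counting as mismatches.

#' Fetch a substitution matrix by name
#'
#' Matrices are taken from the collection shipped with Biostrings
#' (BLOSUM45/50/62/80/100, PAM30/40/70/120/250).
#'
#' @param matrix_name e.g. `"BLOSUM62"`.
#' @return integer matrix with residue row/column names.
#' @export
substitution_matrix <- function(matrix_name = "BLOSUM62") {
  key <- paste0("submat_", matrix_name)
  if (!is.null(the[[key]])) return(the[[key]])
  e <- new.env()
  ok <- tryCatch({
    suppressWarnings(data(list = matrix_name, package = "Biostrings", envir = e))
    is.matrix(e[[matrix_name]])
  }, error = function(cond) FALSE)
  if (!isTRUE(ok)) abort(sprintf("unknown substitution matrix '%s'", matrix_name))
  m <- e[[matrix_name]]
  storage.mode(m) <- "integer"
  the[[key]] <- m
  m
}

#' Karlin-Altschul E-value parameters
#'
#' Defaults are the published gapped-BLOSUM62 constants (K = 0.041,
#' lambda = 0.267 per raw score unit); `m` and `n` are the effective query
#' and database lengths in residues.
#'
#' @param K,lam positive Karlin-Altschul constants.
#' @param m,n effective query / database lengths (residues, >= 1).
#' @return a list of class `evalue_params`.
#' @export
evalue_params <- function(K = 0.041, lam = 0.267, m, n) {
  stopifnot(K > 0, lam > 0, m >= 1, n >= 1)
  structure(list(K = K, lam = lam, m = m, n = n), class = "evalue_params")
}

#' Expected number of chance alignments at a given score
#'
#' `E = K * m * n * exp(-lambda * S)`; strictly decreasing in the score and
#' linear in either sequence length.
#'
#' @param hit_score raw alignment score (substitution-matrix units).
#' @param params an [evalue_params()] object.
#' @return numeric E-value(s).
#' @export
#' @examples
#' evalue_for(60, evalue_params(m = 50, n = 1e5))
evalue_for <- function(hit_score, params) {
  stopifnot(inherits(params, "evalue_params"))
  params$K * params$m * params$n * exp(-params$lam * hit_score)
}

#' Optimal local protein alignment
#'
#' Smith-Waterman alignment with affine gap penalties. Returns `NULL` when
#' the optimal local score is zero (no positive-scoring alignment exists,
#' e.g. between residue sets that only score negatively against each
#' other). Spans are 0-based half-open. The reported E-value uses the
#' sequence lengths as effective lengths under the default Karlin-Altschul
#' constants unless `evalue` parameters are supplied.
#'
#' @param query,subject protein sequences (character scalars).
#' @param matrix_name substitution matrix name (default BLOSUM62).
#' @param gap_open,gap_extend gap penalties (length-L gap costs
#'   `gap_open + L * gap_extend`); `gap_open >= gap_extend >= 0`.
#' @param query_id,subject_id identifiers recorded in the hit.
#' @param evalue optional [evalue_params()]; defaults to the sequence
#'   lengths.
#' @return one-row tibble (query_id, subject_id, raw_score, identity_pct,
#'   matches, columns, query span, subject span, evalue, frame = 0), or
#'   `NULL`.
#' @export
#' @examples
#' local_align("MKTA", "MQTA")
local_align <- function(query, subject, matrix_name = "BLOSUM62",
                        gap_open = 11, gap_extend = 1,
                        query_id = "query", subject_id = "subject",
                        evalue = NULL) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  mat <- substitution_matrix(matrix_name)
  r <- cpp_align(toupper(query), toupper(subject), mat,
                 paste(rownames(mat), collapse = ""), gap_open, gap_extend,
                 local = TRUE)
  if (!r$found || r$score <= 0) return(NULL)
  ep <- evalue %||% evalue_params(m = nchar(query), n = nchar(subject))
  tibble(
    query_id = query_id, subject_id = subject_id,
    raw_score = r$score, identity_pct = r$identity_pct,
    matches = r$matches, columns = r$columns,
    query_start = r$q_start, query_end = r$q_end,
    subject_start = r$s_start, subject_end = r$s_end,
    evalue = evalue_for(r$score, ep), frame = 0L
  )
}

#' Global percent amino-acid identity
#'
#' Needleman-Wunsch global alignment under the same scoring scheme as
#' [local_align()]; identity is `100 * matches / alignment columns`, gap
#' columns counting as non-matches. Symmetric in its arguments. This is
#' the documented convention for full-protein comparisons such as homolog
#' cutoffs (">70% amino acid sequence identity").
#'
#' @param a,b nonempty protein sequences (character; `b` may be a vector,
#'   in which case a vector of identities is returned).
#' @inheritParams local_align
#' @return numeric identity/identities in `[0, 100]`.
#' @export
#' @examples
#' global_identity("AAAA", "AAAAAAAA") # 50: 4 matches over 8 columns
global_identity <- function(a, b, matrix_name = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  if (length(a) != 1) abort("`a` must be a single sequence")
  if (!nzchar(a) || any(!nzchar(b))) abort("sequences must be nonempty")
  mat <- substitution_matrix(matrix_name)
  alpha <- paste(rownames(mat), collapse = "")
  vapply(toupper(b), function(s) {
    cpp_align(toupper(a), s, mat, alpha, gap_open, gap_extend,
              local = FALSE)$identity_pct
  }, numeric(1), USE.NAMES = FALSE)
}
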