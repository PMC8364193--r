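# Sequence containers are plain tibbles with columns `id`, `seq` and
# optionally `desc`. Alphabet checks are done at the point of use so that
# tables can be built with ordinary dplyr verbs.

PROTEIN_CHARS <- "ACDEFGHIKLMNPQRSTVWYBZXU*"
DNA_IUPAC_CHARS <- "ACGTURYSWKMBDHVN"

#' Build a sequence table
#'
#' Constructs the tibble representation of a set of named sequences used
#' throughout the package and validates it: sequences must be nonempty,
#' ids unique, and residues drawn from the declared alphabet (ambiguity
#' codes `N`/`X` are permitted).
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of sequences (same length as `id`).
#' @param alphabet `"protein"` or `"dna"`.
#' @param desc optional character vector of free-text descriptions.
#' @return A tibble with columns `id`, `seq`, `desc`.
#' @export
#' @examples
#' seq_tbl(c("a", "b"), c("MKT", "MQT"), "protein")
seq_tbl <- function(id, seq, alphabet = c("protein", "dna"), desc = NULL) {
  alphabet <- match.arg(alphabet)
  tbl <- tibble(id = as.character(id), seq = toupper(as.character(seq)),
                desc = if (is.null(desc)) NA_character_ else as.character(desc))
  validate_seq_tbl(tbl, alphabet)
  tbl
}

validate_seq_tbl <- function(tbl, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.data.frame(tbl), all(c("id", "seq") %in% names(tbl)))
  if (nrow(tbl) == 0) return(invisible(tbl))
  if (anyDuplicated(tbl$id)) abort("sequence ids must be unique within a collection")
  if (any(!nzchar(tbl$seq)) || anyNA(tbl$seq)) abort("sequences must be nonempty")
  chars <- if (alphabet == "protein") PROTEIN_CHARS else DNA_IUPAC_CHARS
  bad <- grepl(sprintf("[^%s]", chars), toupper(tbl$seq))
  if (any(bad)) {
    abort(sprintf("sequence(s) %s contain characters outside the %s alphabet",
                  paste(utils::head(tbl$id[bad], 3), collapse = ", "), alphabet))
  }
  invisible(tbl)
}

#' Read a FASTA file into a sequence table
#'
#' @param path path to a (possibly wrapped) FASTA file.
#' @return tibble with columns `id` (first whitespace-delimited token of the
#'   header), `desc` (remainder of the header or `NA`) and `seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), NA_character_)
  tibble(id = id, desc = desc, seq = toupper(as.character(set, use.names = FALSE)))
}

#' Write a sequence table to FASTA
#'
#' @param tbl tibble with `id`, `seq` and optionally `desc` columns.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(tbl, path, width = 60L) {
  headers <- tbl$id
  if ("desc" %in% names(tbl)) {
    has_desc <- !is.na(tbl$desc) & nzchar(tbl$desc)
    headers[has_desc] <- paste(tbl$id[has_desc], tbl$desc[has_desc])
  }
  set <- Biostrings::BStringSet(setNames(tbl$seq, headers))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a FASTQ file into a sequence table
#'
#' Qualities are parsed by the reader but not used by any downstream step
#' (classification is alignment-identity based, not quality aware).
#'
#' @param path path to a 4-line-record FASTQ file.
#' @return tibble with columns `id`, `desc`, `seq`.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), NA_character_)
  tibble(id = id, desc = desc, seq = as.character(set, use.names = FALSE))
}

#' Write reads to FASTQ with constant qualities
#'
#' @param tbl tibble with `id` and `seq` columns (DNA).
#' @param path output path.
#' @param quality_char single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(tbl, path, quality_char = "I") {
  set <- Biostrings::DNAStringSet(setNames(tbl$seq, tbl$id))
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(tbl$seq)))
  Biostrings::writeXStringSet(set, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  cpp_revcomp(toupper(as.character(x)))
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames `+1, +2, +3` read the sequence as given; `-1, -2, -3` read the
#' reverse complement from its own 5' end, so frame `-k` of a sequence
#' equals frame `+k` of its reverse complement. Trailing bases that do not
#' fill a codon are dropped, stop codons are rendered `*`, and any codon
#' containing an ambiguity code (including `N`) translates to `X` under the
#' standard genetic code.
#'
#' @param x character vector of DNA sequences, or a sequence table with
#'   `id` and `seq` columns.
#' @return tibble with columns `id`, `frame` (integer in
#'   `-3,-2,-1,+1,+2,+3`) and `peptide`.
#' @export
#' @examples
#' translate_six_frames("ATGGCC")
translate_six_frames <- function(x) {
  if (is.data.frame(x)) {
    ids <- x$id
    seqs <- toupper(x$seq)
  } else {
    seqs <- toupper(as.character(x))
    ids <- names(x) %||% paste0("seq", seq_along(seqs))
  }
  if (any(nchar(seqs) < 3)) {
    abort("sequences shorter than one codon translate to an empty peptide")
  }
  bad <- grepl(sprintf("[^%s]", DNA_IUPAC_CHARS), seqs)
  if (any(bad)) abort("non-IUPAC nucleotide characters in input")
  mat <- cpp_translate_frames(seqs)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  tibble(
    id = rep(ids, times = 6),
    frame = rep(frames, each = length(seqs)),
    peptide = as.vector(mat)
  ) |> dplyr::arrange(.data$id, dplyr::desc(.data$frame >= 0), abs(.data$frame))
}
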