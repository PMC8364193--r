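# helper: reverse-translate a peptide with a fixed arbitrary codon choice
codon_encode <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(protein, "")[[1]], function(a) {
    names(gc)[gc == a][1]
  }, character(1)), collapse = "")
}

test_that("competitive positivity rule: cutoff, decoy competition, ties", {
  marker <- random_protein(80, seed = 61)
  decoy_far <- random_protein(80, seed = 62)           # unrelated decoy
  db <- raw_db(c(m1 = marker), c(d1 = decoy_far))

  # read copied verbatim from the marker: 100% identity, positive
  read_m <- codon_encode(substr(marker, 10, 40))
  r <- classify_read(read_m, db)
  expect_true(r$positive)
  expect_equal(r$marker_identity, 100)
  expect_equal(r$marker_id, "m1")

  # read from a decoy-only region: decoy wins at 100%, marker never reaches
  # the cutoff -> negative
  read_d <- codon_encode(substr(decoy_far, 10, 40))
  expect_false(classify_read(read_d, db)$positive)

  # tie goes to the marker ("greater than or equal"): craft a decoy whose
  # first half IS the marker's first half, and read from that shared region
  shared_decoy <- paste0(substr(marker, 1, 40), random_protein(40, seed = 63))
  db_tie <- raw_db(c(m1 = marker), c(dshare = shared_decoy))
  read_tie <- codon_encode(substr(marker, 5, 35))
  rt <- classify_read(read_tie, db_tie)
  expect_equal(rt$marker_identity, rt$decoy_identity)
  expect_true(rt$positive)

  # a read at ~60% identity to the marker fails the >70% cutoff even with
  # no decoy hit
  variant <- mutate_to_identity(marker, 60, seed = 64)
  read_v <- codon_encode(substr(variant, 10, 40))
  rv <- classify_read(read_v, raw_db(c(m1 = marker), character(0)))
  expect_false(rv$positive)
  if (!is.na(rv$marker_identity)) expect_lt(rv$marker_identity, 70)
})

test_that("too-short reads are flagged, not errors", {
  db <- raw_db(c(m1 = random_protein(50, seed = 65)), character(0))
  r <- classify_read("ACGTACGT", db)   # < 3 * seed_k nucleotides
  expect_true(r$too_short)
  expect_false(r$positive)
})

test_that("classify_read agrees with a literal brute-force oracle", {
  marker <- random_protein(60, seed = 71)
  decoys <- c(d1 = mutate_to_identity(marker, 60, seed = 72),
              d2 = random_protein(55, seed = 73))
  db <- raw_db(c(m1 = marker), decoys)
  withr::with_seed(74, {
    reads <- character(0)
    # reads planted from each database protein plus random reads
    for (src in c(marker, unname(decoys))) {
      for (rep in 1:4) {
        start <- sample(nchar(src) - 20, 1)
        nt <- codon_encode(substr(src, start, start + 19))
        if (runif(1) < 0.5) nt <- reverse_complement(nt)
        reads <- c(reads, nt)
      }
    }
    for (rep in 1:10) {
      reads <- c(reads, paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                              collapse = ""))
    }
    got <- classify_reads(tibble::tibble(id = paste0("r", seq_along(reads)),
                                         seq = reads), db)
    want <- vapply(reads, function(rd) {
      oracle_classify_positive(rd, marker, unname(decoys))
    }, logical(1), USE.NAMES = FALSE)
    expect_equal(got$positive, want)
  })
})

test_that("positive count is monotone in the identity cutoff and decoy set", {
  marker <- random_protein(100, seed = 81)
  v85 <- mutate_to_identity(marker, 85, seed = 82)
  v75 <- mutate_to_identity(marker, 75, seed = 83)
  withr::with_seed(84, {
    reads <- vapply(1:40, function(i) {
      src <- c(marker, v85, v75)[[sample(3, 1)]]
      start <- sample(nchar(src) - 25, 1)
      codon_encode(substr(src, start, start + 24))
    }, character(1))
  })
  tbl <- tibble::tibble(id = paste0("r", 1:40), seq = reads)
  db0 <- raw_db(c(m1 = marker), character(0))

  counts <- vapply(c(50, 60, 70, 80, 90, 99), function(cut) {
    p <- search_params(report_identity_floor_pct = 50,
                       positive_identity_cutoff_pct = cut)
    sum(classify_reads(tbl, db0, p)$positive)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  # adding decoys never increases the positive count
  far <- random_protein(90, seed = 85)
  n0 <- sum(classify_reads(tbl, db0)$positive)
  n1 <- sum(classify_reads(tbl, raw_db(c(m1 = marker), c(d = far)))$positive)
  v60 <- mutate_to_identity(marker, 60, seed = 86)
  n2 <- sum(classify_reads(tbl, raw_db(c(m1 = marker),
                                       c(d = far, d60 = v60)))$positive)
  expect_lte(n1, n0)
  expect_lte(n2, n1)
})

test_that("screen_sample tallies each read at most once", {
  marker <- random_protein(90, seed = 91)
  db <- raw_db(c(m1 = marker, m2 = marker), character(0)) # two identical markers
  read <- codon_encode(substr(marker, 20, 50))
  scr <- screen_sample(tibble::tibble(id = "r1", seq = read), db)
  expect_equal(scr$total_reads, 1)
  expect_equal(scr$positive_reads, 1)

  expect_warning(z <- screen_sample(tibble::tibble(id = character(),
                                                   seq = character()), db),
                 "zero reads")
  expect_equal(z$total_reads, 0)
  expect_equal(z$positive_reads, 0)
})

test_that("seeded search equals seedless search on small inputs", {
  marker <- random_protein(70, seed = 95)
  decoy <- mutate_to_identity(marker, 60, seed = 96)
  db <- raw_db(c(m1 = marker), c(d1 = decoy))
  withr::with_seed(97, {
    reads <- vapply(1:25, function(i) {
      src <- if (i %% 2) marker else decoy
      start <- sample(nchar(src) - 18, 1)
      codon_encode(substr(src, start, start + 17))
    }, character(1))
  })
  tbl <- tibble::tibble(id = paste0("r", 1:25), seq = reads)
  seeded <- classify_reads(tbl, db, search_params(seed_k = 5))
  seedless <- classify_reads(tbl, db, search_params(seed_k = 0))
  # seeding may only drop hits that contain no exact k-mer match - all far
  # below the positive cutoff - so positive calls agree, and whenever the
  # seeded path reports a hit it is the same hit the seedless path finds
  expect_equal(seeded$positive, seedless$positive)
  found <- !is.na(seeded$marker_identity)
  expect_equal(seeded$marker_identity[found], seedless$marker_identity[found])
  expect_equal(seeded$decoy_id[!is.na(seeded$decoy_id)],
               seedless$decoy_id[!is.na(seeded$decoy_id)])
})
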