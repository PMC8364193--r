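test_that("mutate_to_identity hits its target band deterministically", {
  prot <- random_protein(200, seed = 201)
  expect_equal(mutate_to_identity(prot, 100, seed = 1), prot)

  v60 <- mutate_to_identity(prot, 60, seed = 2)
  id <- global_identity(v60, prot)
  expect_gte(id, 58)
  expect_lte(id, 62)

  expect_equal(mutate_to_identity(prot, 60, seed = 2), v60)
  expect_false(mutate_to_identity(prot, 60, seed = 3) == v60)

  # unreachable targets error after bounded attempts
  expect_error(mutate_to_identity("MKT", 10, seed = 4), "could not reach")
})

test_that("community carriage ground truth matches the requested rates", {
  base <- list(n_genomes = 30, genome_length_bp = 5000,
               marker_protein = random_protein(150, seed = 211),
               n_decoy_genes_per_genome = 1L, n_decoy_variants = 2L,
               n_reads = 1000L)
  spec0 <- do.call(community_spec, c(base, list(marker_carriage_rate = 0, seed = 212)))
  c0 <- simulate_community(spec0)
  expect_equal(c0$truth$true_ratio, 0)
  expect_false(any(c0$truth$regions$role == "marker"))

  spec1 <- do.call(community_spec, c(base, list(marker_carriage_rate = 1, seed = 213)))
  c1 <- simulate_community(spec1)
  expect_equal(c1$truth$true_ratio, 1.0)
  expect_equal(sum(c1$truth$marker_copies), 30)

  # binomial carriage at intermediate rates, same seed reproducible
  spec <- do.call(community_spec, c(base, list(marker_carriage_rate = 0.3, seed = 214)))
  ca <- simulate_community(spec)
  cb <- simulate_community(spec)
  expect_equal(ca$truth$true_ratio, cb$truth$true_ratio)
  expect_equal(ca$genomes$seq, cb$genomes$seq)
  n <- sum(ca$truth$marker_copies)
  expect_lt(abs(n - 30 * 0.3), 3 * sqrt(30 * 0.3 * 0.7) + 1)

  # decoy proteins fall in the requested identity band
  ids <- global_identity(spec$marker_protein, ca$decoy_proteins$seq)
  expect_true(all(ids > 50 & ids < 65))
})

test_that("read simulation is length-proportional and deterministic", {
  spec <- community_spec(n_genomes = 20, genome_length_bp = 6000,
                         marker_carriage_rate = 0.5,
                         marker_protein = random_protein(200, seed = 221),
                         n_decoy_genes_per_genome = 0, n_reads = 20000,
                         substitution_error_rate = 0, seed = 222)
  comm <- simulate_community(spec)
  reads <- simulate_reads(comm)
  expect_equal(nrow(reads), 20000)
  expect_true(all(nchar(reads$seq) == spec$read_length_nt))

  # marker-origin fraction ~ copies * (L_gene + L_read - 6) / total bp
  n_copies <- sum(comm$truth$marker_copies)
  gene_len <- 3 * (nchar(spec$marker_protein) + 1)
  p_exp <- n_copies * (gene_len + spec$read_length_nt - 6) /
    sum(nchar(comm$genomes$seq))
  n_marker <- sum(reads$origin == "marker")
  expect_lt(abs(n_marker - 20000 * p_exp), 3 * sqrt(20000 * p_exp) + 1)

  # an error-free read fully inside a marker region classifies positive
  db <- raw_db(c(m = spec$marker_protein), character(0))
  inside <- reads[reads$origin == "marker", ]
  reg <- comm$truth$regions[comm$truth$regions$role == "marker", ]
  full <- dplyr::inner_join(inside, reg, by = "genome",
                            relationship = "many-to-many", suffix = c("", "_r"))
  full <- full[full$start >= full$start_r &
                 full$start + spec$read_length_nt <= full$end, ]
  expect_gt(nrow(full), 0)
  cls <- classify_reads(full[1:min(10, nrow(full)), c("id", "seq")], db)
  expect_true(all(cls$positive))

  # byte-identical FASTQ under a fixed seed
  r1 <- simulate_reads(comm, seed = 7)
  r2 <- simulate_reads(comm, seed = 7)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r1, f1)
  write_fastq(r2, f2)
  expect_equal(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
})

test_that("cohorts pair metagenomes, expression-weighted transcriptomes and metabolites", {
  spec <- community_spec(n_genomes = 12, genome_length_bp = 4000,
                         marker_carriage_rate = 0.15,
                         marker_protein = random_protein(150, seed = 231),
                         n_decoy_genes_per_genome = 0,
                         n_reads = 80, read_length_nt = 100,
                         expression_multiplier_marker = 100,
                         metabolite_effect_size = 1, seed = 232)
  coh <- simulate_cohort(8, spec)
  expect_length(coh$samples, 8)
  expect_equal(nrow(coh$metabolites), 8)
  expect_setequal(coh$metabolites$true_positive, coh$truth$true_positive)

  # transcriptome read sets over-represent marker-origin reads in truly
  # positive samples
  pos <- which(coh$truth$true_positive)
  if (length(pos) > 0) {
    s <- coh$samples[[pos[1]]]
    frac_mg <- mean(s$metagenome$origin == "marker")
    frac_mt <- mean(s$transcriptome$origin == "marker")
    expect_gt(frac_mt, frac_mg)
  }

  # sparse metagenome depth plus strong expression yields gene-negative /
  # transcript-positive samples: expected metagenome marker reads < 1 while
  # expected transcript marker reads > 5
  if (length(pos) > 0) {
    gene_len <- 3 * (nchar(spec$marker_protein) + 1)
    exp_mg <- spec$n_reads * gene_len / (12 * 4000)
    expect_lt(exp_mg, 1)
    w_marker <- spec$expression_multiplier_marker * gene_len
    exp_mt <- spec$n_reads * w_marker / (12 * 4000 + w_marker)
    expect_gt(exp_mt, 5)
    any_gneg_tpos <- any(vapply(pos, function(i) {
      s <- coh$samples[[i]]
      sum(s$metagenome$origin == "marker") == 0 &&
        sum(s$transcriptome$origin == "marker") > 0
    }, logical(1)))
    expect_true(any_gneg_tpos || length(pos) < 2)
  }

  # metabolite shift direction: positives drawn from the lower distribution
  expect_true(is.numeric(coh$metabolites$gbb))
  expect_true(all(coh$metabolites$gbb > 0))
})
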