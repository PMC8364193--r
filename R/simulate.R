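# Synthetic communities with ground truth. Genomes are random sense-codon
# background DNA into which marker and decoy-homolog coding sequences are
# planted; reads are length-proportional substitution-error short reads;
# cohorts add paired transcriptomes (marker expression re-weighted) and
# log-normal metabolite tables shifted down in truly marker-positive
# samples. Everything is deterministic given the spec seed.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Random protein sequence
#'
#' Uniform over the 20 standard residues after an initial methionine.
#'
#' @param length protein length in residues (>= 2).
#' @param seed RNG seed.
#' @return character scalar.
#' @export
random_protein <- function(length, seed = 1) {
  stopifnot(length >= 2)
  withr::with_seed(seed, {
    paste0("M", paste(sample(AA20, length - 1, replace = TRUE), collapse = ""))
  })
}

#' Community simulation spec
#'
#' Defaults are the survey conditions the pipeline is validated under: a
#' 5,000-genome community of 50-kb genomes in which marker carriage is
#' 1 gene per 1,000 genomes (the abundance scale observed for bbuA in
#' stool metagenomes), decoy homolog genes at 50-65% identity in every
#' genome, and 2 million 150-nt reads with 0.5% substitution errors.
#'
#' @param n_genomes number of genomes.
#' @param genome_length_bp genome length (bp; equal across genomes).
#' @param genes_per_genome nominal background gene count per genome (the
#'   background is random sense codons, so this only sets the nominal gene
#'   length used in reports).
#' @param marker_protein marker protein sequence (character scalar;
#'   default a seed-derived 400-residue random protein).
#' @param marker_carriage_rate expected marker genes per genome in `[0, 1]`
#'   (each genome independently carries one copy with this probability).
#' @param decoy_identity_band numeric `c(lo, hi)` percent-identity band
#'   for decoy homolog proteins.
#' @param n_decoy_genes_per_genome decoy homolog genes planted per genome.
#' @param n_decoy_variants number of distinct decoy protein variants the
#'   community shares (planted genes sample from these).
#' @param read_length_nt read length.
#' @param substitution_error_rate per-base substitution error rate.
#' @param n_reads reads per metagenome sample.
#' @param expression_multiplier_marker relative transcription rate of
#'   marker regions in transcriptome read sets.
#' @param metabolite_effect_size standardized downward shift (in log-scale
#'   SD units) of the gamma-butyrobetaine level in marker-positive
#'   samples.
#' @param seed RNG seed fixing all downstream randomness.
#' @return list of class `community_spec`.
#' @export
community_spec <- function(n_genomes = 5000,
                           genome_length_bp = 50000,
                           genes_per_genome = max(1L, genome_length_bp %/% 1200L),
                           marker_protein = NULL,
                           marker_carriage_rate = 1e-3,
                           decoy_identity_band = c(50, 65),
                           n_decoy_genes_per_genome = 1,
                           n_decoy_variants = 4,
                           read_length_nt = 150,
                           substitution_error_rate = 0.005,
                           n_reads = 2e6,
                           expression_multiplier_marker = 50,
                           metabolite_effect_size = 1,
                           seed = 1) {
  if (is.null(marker_protein)) marker_protein <- random_protein(400, seed = 9001)
  stopifnot(n_genomes >= 1, genome_length_bp >= 3,
            marker_carriage_rate >= 0, marker_carriage_rate <= 1,
            length(decoy_identity_band) == 2,
            decoy_identity_band[1] > 0, decoy_identity_band[2] < 100,
            decoy_identity_band[1] < decoy_identity_band[2],
            n_decoy_genes_per_genome >= 0, n_decoy_variants >= 1,
            read_length_nt >= 3, substitution_error_rate >= 0,
            substitution_error_rate <= 1, n_reads >= 1,
            expression_multiplier_marker >= 1, metabolite_effect_size >= 0)
  if (3 * (nchar(marker_protein) + 1) > genome_length_bp) {
    abort("marker coding sequence is longer than the genome")
  }
  structure(list(
    n_genomes = as.integer(n_genomes),
    genome_length_bp = as.integer(genome_length_bp),
    genes_per_genome = as.integer(genes_per_genome),
    marker_protein = toupper(marker_protein),
    marker_carriage_rate = marker_carriage_rate,
    decoy_identity_band = decoy_identity_band,
    n_decoy_genes_per_genome = as.integer(n_decoy_genes_per_genome),
    n_decoy_variants = as.integer(n_decoy_variants),
    read_length_nt = as.integer(read_length_nt),
    substitution_error_rate = substitution_error_rate,
    n_reads = as.integer(n_reads),
    expression_multiplier_marker = expression_multiplier_marker,
    metabolite_effect_size = metabolite_effect_size,
    seed = as.integer(seed)), class = "community_spec")
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + i * 7919) %% (.Machine$integer.max - 1L)) + 1L
}

#' Mutate a protein to a target global identity
#'
#' Substitutes residues at random positions (each replaced by one of the
#' 19 alternatives; no indels) until the global identity of the variant to
#' the original falls within `tolerance` points of the target.
#' Deterministic given the seed; errors after `max_attempts` when the
#' target is unreachable (e.g. very low targets on short proteins).
#'
#' @param protein protein sequence (character scalar).
#' @param target_identity_pct target identity in (0, 100].
#' @param seed RNG seed.
#' @param tolerance acceptance half-width in identity points (default 2).
#' @param max_attempts bounded number of resampling attempts.
#' @return variant protein sequence.
#' @export
mutate_to_identity <- function(protein, target_identity_pct, seed = 1,
                               tolerance = 2, max_attempts = 60) {
  stopifnot(target_identity_pct > 0, target_identity_pct <= 100)
  protein <- toupper(protein)
  if (target_identity_pct >= 100) return(protein)
  chars <- strsplit(protein, "")[[1]]
  L <- length(chars)
  withr::with_seed(seed, {
    m <- max(1L, round(L * (100 - target_identity_pct) / 100))
    for (attempt in seq_len(max_attempts)) {
      m <- min(max(m, 1L), L)
      pos <- sample.int(L, m)
      variant <- chars
      for (p in pos) {
        alt <- AA20[AA20 != chars[p]]
        variant[p] <- alt[sample.int(19, 1)]
      }
      vseq <- paste(variant, collapse = "")
      ident <- global_identity(vseq, protein)
      if (abs(ident - target_identity_pct) <= tolerance) return(vseq)
      step <- round(L * (ident - target_identity_pct) / 100)
      if (step == 0) step <- sign(ident - target_identity_pct)
      m <- m + step
    }
    abort(sprintf(
      "could not reach %g%% identity within +/-%g points in %d attempts",
      target_identity_pct, tolerance, max_attempts))
  })
}

# sample synonymous codons for a protein; appends one stop codon
protein_to_cds <- function(protein) {
  gc <- Biostrings::GENETIC_CODE
  chars <- strsplit(toupper(protein), "")[[1]]
  codons <- vapply(chars, function(a) {
    opts <- names(gc)[gc == a]
    if (length(opts) == 0) abort(sprintf("no codon for residue '%s'", a))
    opts[sample.int(length(opts), 1)]
  }, character(1))
  stops <- names(gc)[gc == "*"]
  paste0(paste(codons, collapse = ""), stops[sample.int(length(stops), 1)])
}

#' Simulate a genome community with planted marker and decoy genes
#'
#' Each genome is random sense-codon background DNA; with probability
#' `marker_carriage_rate` it carries one marker coding sequence at a
#' random position and strand, and it always carries
#' `n_decoy_genes_per_genome` coding sequences of decoy protein variants
#' mutated into the identity band. Ground truth records every placement.
#'
#' @param spec a [community_spec()].
#' @return list of class `sim_community`: `genomes` (sequence tibble),
#'   `decoy_proteins` (sequence tibble: the candidate decoy pool),
#'   `truth` (list: `regions` tibble of 0-based half-open planted spans,
#'   `marker_copies` per genome, `true_ratio` = total marker copies /
#'   n_genomes), and the `spec`.
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  withr::with_seed(spec$seed, {
    band <- spec$decoy_identity_band
    pad <- min(2.5, diff(band) / 2)
    targets <- runif(spec$n_decoy_variants, band[1] + pad, band[2] - pad)
    decoy_prots <- vapply(seq_len(spec$n_decoy_variants), function(i) {
      mutate_to_identity(spec$marker_protein, targets[i],
                         seed = derive_seed(spec$seed, i))
    }, character(1))
    decoy_ids <- sprintf("decoy_variant_%02d", seq_len(spec$n_decoy_variants))

    marker_cds <- protein_to_cds(spec$marker_protein)
    decoy_cds <- vapply(decoy_prots, protein_to_cds, character(1),
                        USE.NAMES = FALSE)

    n_codons <- spec$genome_length_bp %/% 3L
    genomes <- cpp_random_codons(spec$n_genomes, n_codons)
    G <- 3L * n_codons

    carriers <- rbinom(spec$n_genomes, 1, spec$marker_carriage_rate) == 1
    reg_genome <- integer(0); reg_start <- integer(0); reg_end <- integer(0)
    reg_strand <- character(0); reg_role <- character(0); reg_prot <- character(0)

    for (g in seq_len(spec$n_genomes)) {
      genes <- character(0); roles <- character(0); prots <- character(0)
      if (carriers[g]) {
        genes <- marker_cds; roles <- "marker"; prots <- "marker"
      }
      if (spec$n_decoy_genes_per_genome > 0) {
        vi <- sample.int(spec$n_decoy_variants, spec$n_decoy_genes_per_genome,
                         replace = TRUE)
        genes <- c(genes, decoy_cds[vi])
        roles <- c(roles, rep("decoy", length(vi)))
        prots <- c(prots, decoy_ids[vi])
      }
      if (length(genes) == 0) next
      placed <- matrix(numeric(0), ncol = 2)
      gseq <- genomes[g]
      for (k in seq_along(genes)) {
        len <- nchar(genes[k])
        if (len > G) abort("planted gene longer than genome")
        for (try in 1:200) {
          s <- sample.int(G - len + 1L, 1) - 1L   # 0-based start
          if (nrow(placed) == 0 ||
              all(s + len <= placed[, 1] | s >= placed[, 2])) break
          if (try == 200) abort("could not place genes without overlap")
        }
        placed <- rbind(placed, c(s, s + len))
        strand <- if (runif(1) < 0.5) "+" else "-"
        ins <- if (strand == "+") genes[k] else reverse_complement(genes[k])
        substr(gseq, s + 1L, s + len) <- ins
        reg_genome <- c(reg_genome, g); reg_start <- c(reg_start, s)
        reg_end <- c(reg_end, s + len); reg_strand <- c(reg_strand, strand)
        reg_role <- c(reg_role, roles[k]); reg_prot <- c(reg_prot, prots[k])
      }
      genomes[g] <- gseq
    }

    genome_ids <- sprintf("genome_%05d", seq_len(spec$n_genomes))
    regions <- tibble(genome = reg_genome, genome_id = genome_ids[reg_genome],
                      start = reg_start, end = reg_end, strand = reg_strand,
                      role = reg_role, protein_id = reg_prot)
    marker_copies <- tabulate(regions$genome[regions$role == "marker"],
                              nbins = spec$n_genomes)
    structure(list(
      genomes = tibble(id = genome_ids, seq = as.character(genomes)),
      decoy_proteins = tibble(id = decoy_ids, seq = decoy_prots),
      truth = list(regions = regions, marker_copies = marker_copies,
                   true_ratio = sum(marker_copies) / spec$n_genomes),
      spec = spec), class = "sim_community")
  })
}

#' @export
print.sim_community <- function(x, ...) {
  cat(sprintf(
    "sim_community: %d genomes of %d bp; %d marker copies (true ratio %.4g genes/genome), %d planted decoy genes\n",
    x$spec$n_genomes, x$spec$genome_length_bp,
    sum(x$truth$marker_copies), x$truth$true_ratio,
    sum(x$truth$regions$role == "decoy")))
  invisible(x)
}

#' Simulate shotgun reads from a community
#'
#' Read start positions are uniform over the concatenated community
#' (length-proportional per genome), strand uniform, with independent
#' per-base substitution errors. For transcriptome read sets,
#' `expression_multiplier > 1` re-weights marker regions so marker reads
#' are over-represented relative to their genomic share. Each read carries
#' an origin tag: `marker` if it overlaps a planted marker region by at
#' least one codon (3 nt), else `decoy` likewise, else `background`.
#'
#' @param community a [simulate_community()] result.
#' @param n_reads,read_length_nt,error_rate overrides of the community
#'   spec.
#' @param expression_multiplier marker-region weight multiplier (1 =
#'   metagenome; the spec's `expression_multiplier_marker` is the usual
#'   transcriptome setting).
#' @param seed RNG seed (default derived from the spec seed).
#' @return tibble: `id`, `seq`, `genome`, `start` (0-based), `strand`,
#'   `origin`.
#' @export
simulate_reads <- function(community, n_reads = NULL, read_length_nt = NULL,
                           error_rate = NULL, expression_multiplier = 1,
                           seed = NULL) {
  stopifnot(inherits(community, "sim_community"))
  spec <- community$spec
  n_reads <- as.integer(n_reads %||% spec$n_reads)
  rl <- as.integer(read_length_nt %||% spec$read_length_nt)
  er <- error_rate %||% spec$substitution_error_rate
  seed <- seed %||% derive_seed(spec$seed, 555)
  stopifnot(n_reads >= 1, rl >= 3, expression_multiplier >= 1)
  glen <- nchar(community$genomes$seq)
  if (any(rl > glen)) abort("read length exceeds genome length")

  ng <- nrow(community$genomes)
  src_genome <- seq_len(ng) - 1L
  src_lo <- rep(0L, ng)
  src_hi <- glen - rl
  src_w <- as.numeric(glen)
  if (expression_multiplier > 1) {
    mreg <- community$truth$regions[community$truth$regions$role == "marker", ]
    if (nrow(mreg) > 0) {
      src_genome <- c(src_genome, mreg$genome - 1L)
      src_lo <- c(src_lo, pmax(0L, mreg$start - rl + 3L))
      src_hi <- c(src_hi, pmin(glen[mreg$genome] - rl, mreg$end - 3L))
      src_w <- c(src_w, (expression_multiplier - 1) * (mreg$end - mreg$start))
    }
  }

  sampled <- withr::with_seed(seed, {
    cpp_sample_reads(community$genomes$seq, src_genome, src_lo, src_hi,
                     src_w, n_reads, rl, er)
  })
  reads <- tibble(
    id = sprintf("read_%07d", seq_len(n_reads)),
    seq = sampled$read, genome = sampled$genome,
    start = sampled$start, strand = sampled$strand)

  regions <- community$truth$regions
  if (nrow(regions) > 0) {
    ov <- dplyr::inner_join(
      tibble(row = seq_len(n_reads), genome = reads$genome,
             start = reads$start),
      regions[, c("genome", "start", "end", "role")],
      by = "genome", suffix = c("", "_reg"),
      relationship = "many-to-many")
    ov <- ov[pmin(ov$start + rl, ov$end) - pmax(ov$start, ov$start_reg) >= 3, ]
    origin <- rep("background", n_reads)
    if (nrow(ov) > 0) {
      decoy_rows <- unique(ov$row[ov$role == "decoy"])
      marker_rows <- unique(ov$row[ov$role == "marker"])
      origin[decoy_rows] <- "decoy"
      origin[marker_rows] <- "marker"   # marker tag wins on double overlap
    }
    reads$origin <- origin
  } else {
    reads$origin <- "background"
  }
  reads
}

#' Simulate a cohort of paired metagenome / metatranscriptome samples
#'
#' Each sample is an independent community under the shared spec
#' (seed-derived), with a metagenome read set, a transcriptome read set in
#' which marker regions are re-weighted by
#' `expression_multiplier_marker`, and a gamma-butyrobetaine level drawn
#' log-normal with the log-scale location shifted down by
#' `metabolite_effect_size` SD units when the sample truly carries the
#' marker.
#'
#' @param n_samples number of samples (>= 2).
#' @param spec shared [community_spec()].
#' @param seed cohort-level seed.
#' @param n_transcriptome_reads transcriptome depth (default = metagenome
#'   depth).
#' @param gbb_meanlog,gbb_sdlog log-normal parameters of the
#'   marker-negative metabolite distribution (arbitrary concentration
#'   units).
#' @return list of class `sim_cohort`: `samples` (list of per-sample
#'   lists with `community`, `metagenome`, `transcriptome`), `metabolites`
#'   tibble (`sample_id`, `gbb`, `true_positive`), and `truth` tibble.
#' @export
simulate_cohort <- function(n_samples, spec, seed = spec$seed,
                            n_transcriptome_reads = NULL,
                            gbb_meanlog = 3, gbb_sdlog = 0.5) {
  stopifnot(n_samples >= 2, inherits(spec, "community_spec"))
  n_tr <- as.integer(n_transcriptome_reads %||% spec$n_reads)
  samples <- vector("list", n_samples)
  true_pos <- logical(n_samples)
  for (i in seq_len(n_samples)) {
    s_spec <- spec
    s_spec$seed <- derive_seed(seed, i * 13)
    comm <- simulate_community(s_spec)
    mg <- simulate_reads(comm, seed = derive_seed(seed, i * 13 + 1))
    mt <- simulate_reads(comm, n_reads = n_tr,
                         expression_multiplier = spec$expression_multiplier_marker,
                         seed = derive_seed(seed, i * 13 + 2))
    samples[[i]] <- list(community = comm, metagenome = mg, transcriptome = mt)
    true_pos[i] <- sum(comm$truth$marker_copies) > 0
  }
  gbb <- withr::with_seed(derive_seed(seed, 999999L), {
    rlnorm(n_samples,
           meanlog = gbb_meanlog -
             spec$metabolite_effect_size * gbb_sdlog * as.numeric(true_pos),
           sdlog = gbb_sdlog)
  })
  sample_ids <- sprintf("sample_%03d", seq_len(n_samples))
  structure(list(
    samples = setNames(samples, sample_ids),
    metabolites = tibble(sample_id = sample_ids, gbb = gbb,
                         true_positive = true_pos),
    truth = tibble(sample_id = sample_ids, true_positive = true_pos,
                   true_ratio = vapply(samples, function(s)
                     s$community$truth$true_ratio, numeric(1)))),
    class = "sim_cohort")
}
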