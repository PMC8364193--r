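test_that("greedy clustering obeys its contract on simple inputs", {
  one <- seq_tbl("a", "MKTAYIAKQRQISFVK", "protein")
  cl <- cluster_by_identity(one, 50)
  expect_equal(cl$representatives, "a")
  expect_equal(cl$membership$representative, "a")

  two <- seq_tbl(c("a", "b"), rep("MKTAYIAKQRQISFVK", 2), "protein")
  cl2 <- cluster_by_identity(two, 50)
  expect_length(cl2$representatives, 1)
  expect_equal(unique(cl2$membership$representative), cl2$representatives)

  # two long sequences at ~40% identity cannot merge at threshold 50
  base <- random_protein(100, seed = 5)
  far <- mutate_to_identity(base, 40, seed = 6)
  cl3 <- cluster_by_identity(seq_tbl(c("a", "b"), c(base, far), "protein"), 50)
  expect_length(cl3$representatives, 2)

  expect_error(cluster_by_identity(seq_tbl("x", "MK", "protein")[0, ], 50),
               "empty")
})

test_that("cluster count does not increase when the threshold is relaxed", {
  base <- random_protein(80, seed = 21)
  seqs <- seq_tbl(
    paste0("v", 1:8),
    c(base,
      vapply(seq(45, 90, length.out = 7), function(t) {
        mutate_to_identity(base, t, seed = round(t))
      }, character(1))),
    "protein")
  counts <- vapply(c(90, 70, 50, 30), function(th) {
    length(cluster_by_identity(seqs, th)$representatives)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # every member is assigned to a representative at >= threshold identity
  cl <- cluster_by_identity(seqs, 50)
  expect_setequal(cl$membership$id, seqs$id)
  expect_true(all(cl$membership$identity_to_rep >= 50))
})

test_that("homolog calls use a strict >70% cutoff", {
  markers <- seq_tbl("m", "AAAAAAAVVV", "protein")
  expect_true(is_homolog("AAAAAAAVVV", markers))
  # exactly 70% identity (7 matches over 10 ungapped columns) is NOT a homolog
  expect_equal(global_identity("AAAAAAAWWW", "AAAAAAAVVV"), 70)
  expect_false(is_homolog("AAAAAAAWWW", markers))
  expect_false(is_homolog("AAAAAWWWWW", markers))
})

test_that("negative-control construction follows the three steps", {
  marker <- random_protein(150, seed = 31)
  markers <- seq_tbl("marker", marker, "protein")

  # an exact copy of a marker is excluded as a homolog
  pool <- seq_tbl("copy", marker, "protein")
  expect_warning(db <- build_marker_db(markers, pool), "empty")
  expect_equal(nrow(db$decoys), 0)

  # a sequence at ~60% identity is band-included as a decoy
  near <- mutate_to_identity(marker, 60, seed = 32)
  db2 <- build_marker_db(markers, seq_tbl("near60", near, "protein"))
  expect_equal(db2$decoys$id, "near60")

  # empty pool: decoys empty with a warning, pipeline still valid
  expect_warning(db3 <- build_marker_db(markers, markers[0, ]), "empty")
  expect_equal(nrow(db3$decoys), 0)
})

test_that("database invariants hold on randomized pools", {
  withr::with_seed(77, {
    marker <- random_protein(90, seed = 41)
    markers <- seq_tbl("marker", marker, "protein")
    for (rep in 1:5) {
      targets <- runif(6, 30, 95)
      pool <- seq_tbl(
        paste0("p", 1:6),
        vapply(seq_along(targets), function(i) {
          mutate_to_identity(marker, targets[i], seed = rep * 100 + i)
        }, character(1)),
        "protein")
      db <- build_marker_db(markers, pool)
      # no decoy is itself a homolog
      if (nrow(db$decoys) > 0) {
        expect_false(any(is_homolog(db$decoys$seq, markers)))
      }
      # conservation: every pool member is excluded, a decoy, a duplicate,
      # or clustered under a decoy representative
      roles <- db$manifest$role[db$manifest$id %in% pool$id]
      expect_setequal(db$manifest$id, c(markers$id, pool$id))
      expect_true(all(roles %in% c("excluded_homolog", "decoy",
                                   "decoy_duplicate", "clustered_member")))
      # marker and decoy ids disjoint
      expect_length(intersect(db$markers$id, db$decoys$id), 0)
    }
  })
})

test_that("band inclusion can be judged against a single reference marker", {
  m1 <- random_protein(100, seed = 51)
  m2 <- random_protein(100, seed = 52)
  markers <- seq_tbl(c("m1", "m2"), c(m1, m2), "protein")
  near_m2 <- mutate_to_identity(m2, 60, seed = 53)
  pool <- seq_tbl("x", near_m2, "protein")
  # against all markers: in band via m2
  db_all <- build_marker_db(markers, pool)
  expect_true("x" %in% db_all$decoys$id)
  # against m1 alone: far below the band, kept only as cluster representative
  db_ref <- build_marker_db(markers, pool, single_reference = "m1")
  expect_true("x" %in% db_ref$decoys$id)  # it founds its own cluster
  expect_equal(db_ref$manifest$role[db_ref$manifest$id == "x"], "decoy")
})
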