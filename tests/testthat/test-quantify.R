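toy_db <- function() {
  set.seed(202)
  db <- tibble::tibble(
    cluster_id = sprintf("CL%d", 1:4),
    clade = c("subspA", "subspA", "subspB", "subspB"),
    presence_fraction = 1,
    sequence = vapply(1:4, function(i) random_seq(200), ""))
  build_marker_db(db)
}

test_that("verbatim reads map with identity 1 to their marker", {
  db <- toy_db()
  read <- substr(db$sequence[db$clade == "subspA"][1], 21, 120)
  hits <- map_reads(read, db)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 1)
  expect_equal(hits$clade, "subspA")
  expect_equal(hits$aligned_bases, 100)
  # reverse-complemented reads map identically
  hits_rc <- map_reads(as.character(submarker:::revcomp_cpp(read)), db)
  expect_equal(hits_rc$marker_id, hits$marker_id)
  expect_equal(hits_rc$identity, 1)
})

test_that("reads equidistant between clades go to the species pool", {
  set.seed(203)
  shared <- random_seq(120)
  db <- build_marker_db(tibble::tibble(
    cluster_id = c("CL1", "CL2"), clade = c("subspA", "subspB"),
    presence_fraction = 1,
    sequence = c(paste0(shared, random_seq(80)),
                 paste0(shared, random_seq(80)))))
  hits <- map_reads(substr(shared, 11, 110), db)
  expect_equal(hits$clade, "species")
  expect_true(is.na(hits$marker_id))
})

test_that("reads from one subspecies' markers stay in that subspecies", {
  db <- toy_db()
  a_markers <- db$sequence[db$clade == "subspA"]
  set.seed(204)
  reads <- vapply(1:500, function(i) {
    m <- sample(a_markers, 1)
    s <- sample.int(nchar(m) - 99, 1)
    as.character(submarker:::mutate_seqs_cpp(substr(m, s, s + 99), 0.01))
  }, "")
  hits <- map_reads(reads, db)
  expect_gt(nrow(hits), 400)
  expect_gte(mean(hits$clade == "subspA"), 0.99)
})

test_that("profiles conserve mass and handle degenerate input", {
  db <- toy_db()
  empty <- map_reads(character(0), db)
  prof0 <- estimate_abundance(empty, db, read_count_total = 0)
  expect_equal(sum(prof0$relative_abundance), 100, tolerance = 1e-6)
  expect_equal(prof0$relative_abundance[prof0$clade == "other"], 100)

  # unmapped-only sample
  set.seed(205)
  prof1 <- estimate_abundance(map_reads(random_seq(100), db), db,
                              read_count_total = 1)
  expect_equal(sum(prof1$relative_abundance), 100, tolerance = 1e-6)
  expect_equal(prof1$relative_abundance[prof1$clade == "other"], 100)

  # all-marker sample: the mapped mass fraction is ~1, so the source clade
  # takes essentially the whole profile
  reads <- substr(rep(db$sequence[db$clade == "subspA"], each = 3), 1, 150)
  prof2 <- estimate_abundance(map_reads(reads, db), db,
                              read_count_total = length(reads))
  expect_equal(sum(prof2$relative_abundance), 100, tolerance = 1e-6)
  expect_equal(prof2$relative_abundance[prof2$clade == "subspA"], 100)
  expect_equal(prof2$relative_abundance[prof2$clade == "subspB"], 0)
})

test_that("planted mixtures are recovered within tolerance", {
  cfg <- tiny_cfg(61, dropout = 0, n_reads = 60000)
  sim <- simulate_references(cfg)
  pg <- build_pangenome(sim$genomes)
  db <- build_marker_db(
    suppressMessages(filter_specificity(select_candidates(pg), sim$decoys))$markers)

  shares_for <- function(fA, seed) {
    mix <- c(subspA = fA, subspB = 1 - fA)
    mix <- mix[mix > 0]
    rd <- simulate_reads(sim$genomes, mix, cfg, "s", seed = seed)
    prof <- estimate_abundance(map_reads(rd$reads, db), db)
    sh <- clade_shares(prof)
    sh$share[sh$clade == "subspA"]
  }
  est50 <- shares_for(0.5, 71)
  expect_lt(abs(est50 - 0.5) * 100, 5)

  est75 <- shares_for(0.75, 72)  # a 3:1 mixture
  ratio <- est75 / (1 - est75)
  expect_lt(abs(ratio - 3) / 3, 0.15)

  # rank order follows the planted gradient
  grad <- vapply(c(0.1, 0.5, 0.9), shares_for, 1.0, seed = 73)
  expect_equal(order(grad), 1:3)

  # single-subspecies sample: the absent clade stays under the 0.5% floor
  rd <- simulate_reads(sim$genomes, c(subspA = 1), cfg, "s", seed = 74)
  prof <- estimate_abundance(map_reads(rd$reads, db), db)
  sh <- clade_shares(prof)
  expect_lt(100 * sh$share[sh$clade == "subspB"], 0.5)
  expect_false(is_detected(prof, "subspB"))
})

test_that("the detectability floor is boundary-inclusive", {
  prof <- tibble::tibble(sample_id = "s",
                         clade = c("subspA", "subspB", "unclassified", "other"),
                         relative_abundance = c(0.5, 0.49, 0, 99.01))
  expect_true(is_detected(prof, "subspA"))
  expect_false(is_detected(prof, "subspB"))
  prof$relative_abundance <- c(0, 0.99, 0, 99.01)
  expect_false(is_detected(prof, "subspA"))
  expect_error(is_detected(prof, "nope"), "not in profile")
})

test_that("clade shares renormalize within the species", {
  prof <- tibble::tibble(sample_id = "s",
                         clade = c("subspA", "subspB", "unclassified", "other"),
                         relative_abundance = c(6, 3, 1, 90))
  sh <- clade_shares(prof)
  expect_equal(sh$share, c(0.6, 0.3, 0.1))
  sh2 <- clade_shares(prof, include_unclassified = FALSE)
  expect_equal(sh2$share, c(2 / 3, 1 / 3))
})
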