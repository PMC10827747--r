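make_counts_pangenome <- function(rows) {
  # rows: list of c(n_in_A, n_in_B) per cluster, over 14 subspA + 30 subspB
  labels <- c(rep("subspA", 14), rep("subspB", 30))
  names(labels) <- sprintf("G%02d", seq_along(labels))
  presence <- matrix(0L, nrow = length(rows), ncol = length(labels),
                     dimnames = list(sprintf("CL%05d", seq_along(rows)),
                                     names(labels)))
  for (i in seq_along(rows)) {
    presence[i, which(labels == "subspA")[seq_len(rows[[i]][1])]] <- 1L
    if (rows[[i]][2] > 0)
      presence[i, which(labels == "subspB")[seq_len(rows[[i]][2])]] <- 1L
  }
  fake_pangenome(presence, labels)
}

test_that("the 90%/0% rule reproduces the worked selection cases", {
  pg <- make_counts_pangenome(list(c(13, 0),   # 13/14, absent in B -> marker
                                   c(14, 1),   # perfect in A but 1 B genome
                                   c(12, 0),   # 12/14 < 90%
                                   c(14, 0)))  # full presence -> marker
  cand <- select_candidates(pg, presence_threshold = 0.90)
  expect_setequal(cand$cluster_id, c("CL00001", "CL00004"))
  expect_true(all(cand$clade == "subspA"))
  expect_equal(cand$presence_count[cand$cluster_id == "CL00001"], 13)
  expect_error(select_candidates(pg, presence_threshold = 1.2), "0, 1")

  # scan all possible presence counts: the smallest count that qualifies a
  # cluster over 14 target genomes is 13
  ladder <- make_counts_pangenome(lapply(1:14, function(n) c(n, 0)))
  sel <- select_candidates(ladder, presence_threshold = 0.90)
  expect_equal(min(sel$presence_count), 13)
})

test_that("selection equals exhaustive rule application on random matrices", {
  set.seed(123)
  for (rep in 1:50) {
    n_cl <- sample(3:20, 1); n_g <- sample(4:10, 1)
    n_a <- sample(2:(n_g - 2), 1)
    labels <- c(rep("subspA", n_a), rep("subspB", n_g - n_a))
    names(labels) <- sprintf("G%02d", seq_len(n_g))
    presence <- matrix(rbinom(n_cl * n_g, 1, runif(1, 0.2, 0.8)), n_cl, n_g,
                       dimnames = list(sprintf("CL%05d", seq_len(n_cl)),
                                       names(labels)))
    presence[rowSums(presence) == 0, 1] <- 1L  # every cluster in >= 1 genome
    pg <- fake_pangenome(presence, labels)
    got <- select_candidates(pg)[, c("cluster_id", "clade")]
    want <- brute_force_candidates(presence, labels)
    expect_equal(as.data.frame(got[order(got$cluster_id, got$clade), ]),
                 want[order(want$cluster_id, want$clade), ],
                 ignore_attr = TRUE)
  }
})

test_that("raising the presence threshold never adds a candidate", {
  set.seed(9)
  labels <- setNames(rep(c("subspA", "subspB"), c(5, 7)), sprintf("G%02d", 1:12))
  presence <- matrix(rbinom(20 * 12, 1, 0.5), 20, 12,
                     dimnames = list(sprintf("CL%05d", 1:20), names(labels)))
  presence[rowSums(presence) == 0, 1] <- 1L
  pg <- fake_pangenome(presence, labels)
  prev <- NULL
  for (thr in c(0.5, 0.7, 0.9, 1.0)) {
    cur <- select_candidates(pg, thr)$cluster_id
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("unknown and excluded genomes are ignored in counting", {
  labels <- setNames(c(rep("subspA", 3), rep("subspB", 3), "unknown"),
                     sprintf("G%02d", 1:7))
  presence <- matrix(0L, 1, 7, dimnames = list("CL00001", names(labels)))
  presence[1, c(1:3, 7)] <- 1L  # all A genomes + the unknown one
  pg <- fake_pangenome(presence, labels)
  cand <- select_candidates(pg)
  expect_equal(cand$cluster_id, "CL00001")

  # excluding one carrier drops presence to 2/2 (still 100%)
  cand2 <- select_candidates(pg, excluded_genomes = "G01")
  expect_equal(cand2$presence_fraction, 1)
  expect_equal(cand2$n_target, 2L)
})

test_that("specificity filter applies the >90% identity / >50% coverage rule", {
  set.seed(77)
  cand_seq <- random_seq(300)
  cands <- tibble::tibble(cluster_id = c("CLA", "CLB", "CLC"),
                          clade = "subspA",
                          sequence = c(cand_seq, cand_seq, random_seq(300)),
                          length = 300L)
  decoys <- tibble::tibble(
    gene_id = c("hit60", "hit40"),
    sequence = c(
      # ~95% identity over 60% of CLA's length
      as.character(submarker:::mutate_seqs_cpp(substr(cand_seq, 1, 180), 0.04)),
      # same identity but only 40% coverage
      as.character(submarker:::mutate_seqs_cpp(substr(cand_seq, 1, 120), 0.04))))
  res <- suppressMessages(
    filter_specificity(cands[c(1, 3), ], decoys[1, ]))
  expect_equal(res$verdicts$passed, c(FALSE, TRUE))
  expect_equal(res$markers$cluster_id, "CLC")
  expect_equal(res$verdicts$decoy_id[1], "hit60")
  expect_gt(res$verdicts$identity[1], 0.90)
  expect_gt(res$verdicts$query_coverage[1], 0.50)

  res40 <- filter_specificity(cands[2, ], decoys[2, ])
  expect_true(res40$verdicts$passed)
  expect_lt(res40$verdicts$query_coverage, 0.5)

  # no shared k-mers: retained with no best hit
  res_none <- filter_specificity(cands[3, ], decoys[2, ])
  expect_true(res_none$verdicts$passed)
  expect_true(is.na(res_none$verdicts$decoy_id))
})

test_that("candidates shorter than the seed k fall back to full DP", {
  short <- "ACGTTGCAGGCA"  # 12 bp < k = 15
  decoys <- tibble::tibble(gene_id = "d1",
                           sequence = paste0(random_seq(100), short,
                                             random_seq(100)))
  res <- suppressMessages(filter_specificity(
    tibble::tibble(cluster_id = "S", clade = "subspA", sequence = short,
                   length = 12L),
    decoys))
  expect_false(res$verdicts$passed)  # perfect identity, full coverage
  expect_equal(res$verdicts$identity, 1)
})

test_that("marker database construction is deterministic and safe", {
  set.seed(11)
  seqs <- vapply(1:4, function(i) random_seq(100 + 10 * i), "")
  mk <- tibble::tibble(cluster_id = sprintf("CL%d", 1:4),
                       clade = c("subspA", "subspA", "subspB", "subspB"),
                       presence_fraction = 1, sequence = seqs)
  db <- build_marker_db(mk)
  expect_equal(db$marker_id, c("subspA_0001", "subspA_0002",
                               "subspB_0001", "subspB_0002"))
  # ids ordered by descending length within clade
  expect_true(all(diff(db$length[db$clade == "subspA"]) <= 0))

  dup <- mk; dup$sequence[3] <- dup$sequence[1]
  expect_error(build_marker_db(dup), "both clades")
  expect_warning(build_marker_db(mk[mk$clade == "subspA", ]), "unquantifiable")
})

test_that("end-to-end marker recovery matches simulator ground truth", {
  for (seed in c(51, 52)) {
    sim <- simulate_references(tiny_cfg(seed, dropout = 0.07))
    pg <- build_pangenome(sim$genomes)
    cand <- select_candidates(pg)
    res <- suppressMessages(filter_specificity(cand, sim$decoys))
    # map recovered clusters back to planted genes via the representative
    rep_gene <- sim$genomes$gene_id[match(res$markers$sequence,
                                          sim$genomes$sequence)]
    want <- sim$truth$true_markers
    want <- want$gene_id[want$presence_fraction >= 0.9 & !want$decoy_homolog]
    expect_setequal(rep_gene, want)
    # no planted core gene is ever selected
    expect_false(any(grepl("^core", rep_gene)))
  }
})
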