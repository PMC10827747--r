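strain_fixture <- function(seed, genome_ids_n = 2, n_reads = 12000,
                           error_rate = 0, strain_snps = 15) {
  cfg <- tiny_cfg(seed, dropout = 0, strain_snps = strain_snps,
                  n_reads = n_reads, error_rate = error_rate)
  sim <- simulate_references(cfg)
  pg <- build_pangenome(sim$genomes)
  db <- build_marker_db(
    suppressMessages(filter_specificity(select_candidates(pg), sim$decoys))$markers)
  list(cfg = cfg, sim = sim, db = db)
}

sample_from_genome <- function(fx, gid, sid, seed) {
  rd <- simulate_reads(fx$sim$genomes, c(subspA = 1), fx$cfg, sid,
                       seed = seed, genome_ids = gid)
  list(reads = rd$reads, hits = map_reads(rd$reads, fx$db))
}

test_that("deep error-free reads reproduce the source genome's markers", {
  fx <- strain_fixture(81)
  gids <- unique(fx$sim$genomes$genome_id[fx$sim$genomes$label == "subspA"])
  s1 <- sample_from_genome(fx, gids[1], "s1", 301)
  s2 <- sample_from_genome(fx, gids[2], "s2", 302)
  # strain analysis runs on one clade's markers
  dbA <- fx$db[fx$db$clade == "subspA", ]
  aln <- build_consensus(dplyr::bind_rows(s1$hits, s2$hits),
                         dplyr::bind_rows(s1$reads, s2$reads), dbA)
  expect_setequal(aln$samples, c("s1", "s2"))
  dbA <- dbA[dbA$marker_id %in% aln$markers_used$marker_id, ]
  for (i in 1:2) {
    gid <- gids[i]
    truth_seq <- unlist(lapply(dbA$cluster_id, function(cl) {
      gene <- fx$sim$genomes$gene_id[match(dbA$sequence[dbA$cluster_id == cl],
                                           fx$sim$genomes$sequence)]
      s <- fx$sim$genomes$sequence[fx$sim$genomes$genome_id == gid &
                                     fx$sim$genomes$gene_id == gene]
      strsplit(s, "")[[1]]
    }))
    called <- aln$consensus[paste0("s", i), ] != "N"
    expect_gt(mean(called), 0.95)
    expect_equal(aln$consensus[paste0("s", i), called],
                 truth_seq[called], ignore_attr = TRUE)
  }

  # the two strains differ exactly where their marker alleles differ
  truths <- lapply(gids[1:2], function(gid) {
    unlist(lapply(dbA$cluster_id, function(cl) {
      gene <- fx$sim$genomes$gene_id[match(dbA$sequence[dbA$cluster_id == cl],
                                           fx$sim$genomes$sequence)]
      s <- fx$sim$genomes$sequence[fx$sim$genomes$genome_id == gid &
                                     fx$sim$genomes$gene_id == gene]
      strsplit(s, "")[[1]]
    }))
  })
  both <- aln$consensus[1, ] != "N" & aln$consensus[2, ] != "N"
  expect_equal(which(aln$consensus[1, both] != aln$consensus[2, both]),
               which(truths[[1]][both] != truths[[2]][both]))
})

test_that("ambiguous pileups and shallow depth yield N", {
  db <- suppressWarnings(build_marker_db(tibble::tibble(
    cluster_id = "CL1", clade = "subspA", presence_fraction = 1,
    sequence = paste(rep("ACGT", 15), collapse = ""))))
  # two reads covering the same 60 bp, disagreeing at position 1 (50/50)
  v1 <- db$sequence[1]
  v2 <- paste0("T", substr(v1, 2, 60))
  hits <- tibble::tibble(sample_id = "s", read_id = c("r1", "r2"),
                         read_idx = 1:2, marker_id = db$marker_id[1],
                         clade = "subspA",
                         identity = c(1, 59 / 60), aligned_bases = 60L,
                         marker_start = 0L, read_start = 0L, reverse = FALSE)
  reads <- tibble::tibble(sample_id = "s", read_id = c("r1", "r2"),
                          sequence = c(v1, v2))
  aln <- build_consensus(hits, reads, db, min_depth = 2, majority = 0.8,
                         min_marker_count = 1, min_callable = 0.1)
  expect_equal(unname(aln$consensus[1, 1]), "N")  # 50/50 split
  expect_true(all(aln$consensus[1, 2:60] != "N")) # unanimous elsewhere

  # depth below min_depth is never called; with nothing callable the sample
  # is dropped with a warning
  expect_warning(
    aln3 <- build_consensus(hits[1, ], reads[1, ], db, min_depth = 3,
                            majority = 0.8, min_marker_count = 1,
                            min_callable = 0.5),
    "no sample")
  expect_length(aln3$samples, 0)
})

test_that("lowering min_depth never increases N calls", {
  fx <- strain_fixture(82, n_reads = 1500, error_rate = 0.005)
  gid <- unique(fx$sim$genomes$genome_id[fx$sim$genomes$label == "subspA"])[1]
  s <- sample_from_genome(fx, gid, "s1", 303)
  n_at <- vapply(c(2, 5, 10), function(md) {
    aln <- build_consensus(s$hits, s$reads, fx$db, min_depth = md,
                           min_marker_count = 1, min_callable = 0)
    if (length(aln$samples) == 0) Inf else sum(aln$consensus == "N")
  }, 1.0)
  expect_true(all(diff(n_at) >= 0))
})

test_that("pairwise distances follow the comparable-site definition", {
  aln <- structure(list(
    samples = c("a", "b", "c"),
    markers_used = tibble::tibble(marker_id = "m", length = 100L),
    consensus = rbind(a = strsplit(paste(rep("A", 100), collapse = ""), "")[[1]],
                      b = c(rep("C", 5), rep("A", 95)),
                      c = rep("N", 100)),
    depth = matrix(1, 3, 100), marker_of_site = rep("m", 100)),
    class = "strain_alignment")
  aln$consensus["c", 1:2] <- "A"
  dm <- pairwise_distances(aln)
  expect_equal(dm["a", "a"], 0)
  expect_equal(dm["a", "b"], 0.05)   # 5 mismatches over 100 comparable sites
  expect_equal(dm["b", "a"], 0.05)
  expect_equal(dm["a", "c"], 0)      # 2 comparable sites, both equal
  expect_equal(attr(dm, "n_sites")["a", "c"], 2L)

  aln$consensus["c", ] <- "N"
  dm2 <- pairwise_distances(aln)
  expect_true(is.na(dm2["a", "c"]))  # zero comparable sites -> missing
  expect_error(nj_tree(dm2), "missing")
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  dm <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- attr(nj_tree(dm), "phylo")
  # x_a = (d_ab + d_ac - d_bc) / 2, etc.
  want <- c(a = (.3 + .4 - .5) / 2, b = (.3 + .5 - .4) / 2,
            c = (.4 + .5 - .3) / 2)
  got <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(got[names(want)], want, tolerance = 1e-10)
})

test_that("NJ recovers the generating topology from additive matrices", {
  set.seed(90)
  for (rep in 1:10) {
    n_tip <- sample(5:8, 1)
    true_tree <- ape::rtree(n_tip, br = function(n) runif(n, 0.05, 0.5))
    dm <- ape::cophenetic.phylo(true_tree)
    tr <- attr(nj_tree(dm), "phylo")
    expect_equal(ape::dist.topo(ape::unroot(true_tree), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("distances and trees are invariant to sample order", {
  fx <- strain_fixture(83)
  gids <- unique(fx$sim$genomes$genome_id[fx$sim$genomes$label == "subspA"])
  ss <- lapply(1:3, function(i)
    sample_from_genome(fx, gids[i], paste0("s", i), 400 + i))
  hits <- dplyr::bind_rows(lapply(ss, `[[`, "hits"))
  reads <- dplyr::bind_rows(lapply(ss, `[[`, "reads"))
  dbA <- fx$db[fx$db$clade == "subspA", ]
  aln <- build_consensus(hits, reads, dbA)
  dm <- pairwise_distances(aln)
  # shuffled input order
  ord <- c(3, 1, 2)
  aln2 <- build_consensus(dplyr::bind_rows(lapply(ss[ord], `[[`, "hits")),
                          dplyr::bind_rows(lapply(ss[ord], `[[`, "reads")),
                          dbA)
  dm2 <- pairwise_distances(aln2)
  expect_equal(unclass(dm)[rownames(dm), colnames(dm)],
               unclass(dm2)[rownames(dm), colnames(dm)], ignore_attr = TRUE)
  expect_equal(unclass(nj_tree(dm)), unclass(nj_tree(dm2)))
})
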