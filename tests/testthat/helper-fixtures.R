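# small simulation configs shared across test files

tiny_cfg <- function(seed, ...) {
  args <- list(
    n_genomes = c(subspA = 4, subspB = 5),
    core_genes = 25, specific_genes = c(subspA = 10, subspB = 10),
    gene_length_mean = 400, gene_length_sd = 50,
    dropout = 0.1, strain_snps = 5,
    n_reads = 20000, error_rate = 0.005, seed = seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# pangenome object built directly from a presence/absence matrix, for tests
# of the selection rule that need exact counts
fake_pangenome <- function(presence, labels) {
  n_cl <- nrow(presence)
  set.seed(1)
  reps <- vapply(seq_len(n_cl), function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""), "")
  structure(list(
    presence = presence,
    clusters = tibble::tibble(cluster_id = rownames(presence),
                              representative = reps, length = nchar(reps),
                              n_genomes = as.integer(rowSums(presence))),
    genomes = tibble::tibble(genome_id = colnames(presence),
                             label = unname(labels[colnames(presence)])),
    params = list()
  ), class = "pangenome")
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# independent re-statement of the marker selection rule, applied row by row
brute_force_candidates <- function(presence, labels, threshold = 0.9) {
  clades <- sort(setdiff(unique(labels), "unknown"))
  out <- list()
  for (cl_i in 1:2) {
    cl <- clades[cl_i]; other <- clades[3 - cl_i]
    tgt <- names(labels)[labels == cl]
    off <- names(labels)[labels == other]
    need <- ceiling(threshold * length(tgt))
    for (r in rownames(presence)) {
      n_in <- sum(presence[r, tgt])
      n_out <- sum(presence[r, off])
      if (n_in >= need && n_out == 0)
        out[[length(out) + 1]] <- data.frame(cluster_id = r, clade = cl)
    }
  }
  if (length(out) == 0)
    return(data.frame(cluster_id = character(), clade = character()))
  do.call(rbind, out)
}
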