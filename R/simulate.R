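#' Simulation configuration for a two-subspecies pangenome
#'
#' Defines the synthetic study system: two subspecies of one species sharing
#' a mutated core genome plus subspecies-specific gene repertoires, optional
#' mislabeled reference genomes, per-strain SNPs on the specific genes, decoy
#' genes from off-target species (a configurable fraction of which are close
#' homologs of specific genes, to exercise the specificity filter), and
#' substitution-error shotgun reads.
#'
#' Defaults mirror the reference-genome setting the package targets: 14
#' genomes of subspecies A versus 30 of subspecies B, a shared core, ~200
#' specific genes per subspecies with a 7% per-genome dropout (so a typical
#' specific gene is present in about 13 of 14 target genomes), 2% core
#' divergence between subspecies (sister subspecies of one bacterial species
#' sit near 98% average nucleotide identity), 150 bp reads at 0.5%
#' substitution error.
#'
#' @param n_genomes named integer vector: genomes per subspecies.
#' @param core_genes number of core gene clusters shared by all genomes.
#' @param specific_genes named integer vector: subspecies-specific gene
#'   clusters per subspecies.
#' @param gene_length_mean,gene_length_sd gene length distribution (bp).
#' @param core_divergence expected per-base divergence between the two
#'   subspecies' core gene variants.
#' @param dropout per-genome probability that a specific gene is absent.
#' @param n_mislabeled number of genomes built with subspecies B's gene
#'   repertoire but labeled subspecies A (planted mis-annotations).
#' @param decoy_homolog_rate fraction of specific genes that get a close
#'   (~95% identity, full-length) homolog in the decoy set.
#' @param decoy_divergence per-base divergence of planted decoy homologs.
#' @param n_decoy_random number of unrelated random decoy genes.
#' @param strain_snps number of strain-defining SNPs planted on each
#'   genome's specific genes.
#' @param read_length,error_rate,n_reads shotgun read simulation parameters.
#' @param seed mandatory RNG seed; identical config + seed gives identical
#'   output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genomes = c(subspA = 14, subspB = 30),
                       core_genes = 2000,
                       specific_genes = c(subspA = 200, subspB = 200),
                       gene_length_mean = 1000,
                       gene_length_sd = 200,
                       core_divergence = 0.02,
                       dropout = 0.07,
                       n_mislabeled = 0,
                       decoy_homolog_rate = 0.2,
                       decoy_divergence = 0.05,
                       n_decoy_random = 50,
                       strain_snps = 20,
                       read_length = 150,
                       error_rate = 0.005,
                       n_reads = 200000,
                       seed = NULL) {
  if (is.null(seed)) abort("sim_config() requires an explicit seed")
  if (length(n_genomes) != 2 || is.null(names(n_genomes)))
    abort("n_genomes must be a named vector of two subspecies")
  rates <- c(core_divergence, dropout, decoy_homolog_rate, decoy_divergence,
             error_rate)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  structure(list(
    n_genomes = n_genomes, core_genes = core_genes,
    specific_genes = specific_genes, gene_length_mean = gene_length_mean,
    gene_length_sd = gene_length_sd, core_divergence = core_divergence,
    dropout = dropout, n_mislabeled = n_mislabeled,
    decoy_homolog_rate = decoy_homolog_rate,
    decoy_divergence = decoy_divergence, n_decoy_random = n_decoy_random,
    strain_snps = strain_snps, read_length = read_length,
    error_rate = error_rate, n_reads = n_reads, seed = as.integer(seed)
  ), class = "sim_config")
}

random_dna <- function(n_seqs, mean_len, sd_len, min_len = 100L) {
  lens <- pmax(min_len, round(rnorm(n_seqs, mean_len, sd_len)))
  vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
}

#' Simulate two-subspecies reference genomes with ground truth
#'
#' Core genes are shared by every genome (each subspecies carries its own
#' variant, diverged at the configured rate); subspecies-specific genes are
#' present in each target genome minus dropout; optional mislabeled genomes
#' carry the other subspecies' repertoire; per-strain SNPs are planted on
#' specific genes; the decoy set contains close homologs of a configured
#' fraction of the specific genes plus unrelated genes.
#'
#' @param cfg a [sim_config()].
#' @return list with `genomes` (a genome table), `decoys` (tibble `gene_id`,
#'   `sequence`), and `truth` (gene-to-cluster map, realized presence per
#'   cluster, the realized true marker set, planted mislabeled genome ids,
#'   planted strain SNPs, decoy homolog map).
#' @export
simulate_references <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  clades <- names(cfg$n_genomes)
  with_seed(cfg$seed, {
    # ancestral core, then one variant per subspecies
    core <- random_dna(cfg$core_genes, cfg$gene_length_mean, cfg$gene_length_sd)
    core_ids <- sprintf("core%05d", seq_len(cfg$core_genes))
    core_var <- list(
      mutate_seqs_cpp(core, cfg$core_divergence / 2),
      mutate_seqs_cpp(core, cfg$core_divergence / 2)
    )
    names(core_var) <- clades
    # subspecies-specific genes: unrelated fresh sequences
    spec <- lapply(clades, function(cl) {
      n <- cfg$specific_genes[[cl]]
      tibble(gene_id = sprintf("%s_spec%04d", cl, seq_len(n)),
             sequence = random_dna(n, cfg$gene_length_mean, cfg$gene_length_sd))
    })
    names(spec) <- clades

    # genome layout: which repertoire each genome carries vs how it is labeled
    plan <- bind_rows(
      tibble(label = rep(clades, cfg$n_genomes),
             repertoire = rep(clades, cfg$n_genomes))
    )
    if (cfg$n_mislabeled > 0) {
      plan <- bind_rows(plan,
        tibble(label = clades[1], repertoire = clades[2])[rep(1, cfg$n_mislabeled), ])
    }
    plan$genome_id <- sprintf("G%03d_%s", seq_len(nrow(plan)), plan$label)
    mislabeled <- plan$genome_id[plan$label != plan$repertoire]

    snp_rows <- list()
    genomes <- map_dfr(seq_len(nrow(plan)), function(i) {
      rep_cl <- plan$repertoire[i]
      gid <- plan$genome_id[i]
      keep <- runif(nrow(spec[[rep_cl]])) >= cfg$dropout
      sp <- spec[[rep_cl]][keep, ]
      # strain-defining SNPs on the specific genes
      if (cfg$strain_snps > 0 && nrow(sp) > 0) {
        lens <- nchar(sp$sequence)
        gsel <- sample.int(nrow(sp), cfg$strain_snps, replace = TRUE)
        pos <- vapply(lens[gsel], function(L) sample.int(L, 1), 1L)
        seqs <- sp$sequence
        planted <- tibble(genome_id = gid, gene_id = sp$gene_id[gsel], pos = pos,
                          ref = NA_character_, alt = NA_character_)
        for (s in seq_along(gsel)) {
          g <- gsel[s]
          old <- substr(seqs[g], pos[s], pos[s])
          alt <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
          substr(seqs[g], pos[s], pos[s]) <- alt
          planted$ref[s] <- old
          planted$alt[s] <- alt
        }
        sp$sequence <- seqs
        snp_rows[[length(snp_rows) + 1]] <<- planted
      }
      bind_rows(
        tibble(gene_id = core_ids, sequence = core_var[[rep_cl]]),
        sp
      ) |> mutate(genome_id = gid, label = plan$label[i], .before = 1)
    })
    genomes <- genome_table(genomes)

    # decoys: homologs of a sampled fraction of specific genes + random genes
    all_spec <- bind_rows(spec)
    is_hom <- runif(nrow(all_spec)) < cfg$decoy_homolog_rate
    homolog_of <- all_spec$gene_id[is_hom]
    decoys <- bind_rows(
      tibble(gene_id = paste0("decoy_", homolog_of),
             sequence = mutate_seqs_cpp(all_spec$sequence[is_hom],
                                        cfg$decoy_divergence)),
      tibble(gene_id = sprintf("decoy_rand%04d", seq_len(cfg$n_decoy_random)),
             sequence = random_dna(cfg$n_decoy_random, cfg$gene_length_mean,
                                   cfg$gene_length_sd))
    )

    # ground truth: realized presence per cluster and the realized marker set
    gene_map <- genomes |>
      select("genome_id", "gene_id") |>
      mutate(cluster = .data$gene_id)
    # the realized truth is defined over correctly-labeled genomes: planted
    # mis-annotations are what the outlier detector exists to remove
    clean <- plan |> filter(.data$label == .data$repertoire)
    presence <- genomes |>
      filter(.data$genome_id %in% clean$genome_id) |>
      distinct(.data$genome_id, .data$gene_id) |>
      left_join(select(plan, "genome_id", "label"), by = "genome_id") |>
      count(.data$gene_id, .data$label) |>
      tidyr::pivot_wider(names_from = "label", values_from = "n", values_fill = 0L)
    for (cl in clades) if (!cl %in% names(presence)) presence[[cl]] <- 0L
    n_lab <- table(factor(clean$label, levels = clades))
    true_markers <- map_dfr(seq_along(clades), function(ci) {
      cl <- clades[ci]; other <- clades[-ci]
      presence |>
        filter(startsWith(.data$gene_id, paste0(cl, "_spec")),
               .data[[other]] == 0) |>
        transmute(gene_id = .data$gene_id, clade = cl,
                  presence_fraction = .data[[cl]] / as.integer(n_lab[[cl]]),
                  decoy_homolog = .data$gene_id %in% homolog_of)
    })

    list(
      genomes = genomes,
      decoys = decoys,
      truth = list(
        gene_map = gene_map,
        n_clusters = cfg$core_genes + sum(cfg$specific_genes),
        true_markers = true_markers,
        mislabeled = mislabeled,
        strain_snps = bind_rows(snp_rows),
        decoy_homolog_of = homolog_of
      )
    )
  })
}

#' Simulate a shotgun read mixture with known composition
#'
#' Reads are drawn from whole-genome sequences (the concatenation of each
#' genome's genes) with per-clade read mass proportional to the requested
#' mixture; within a clade, genomes are sampled proportionally to length.
#' Substitution errors only; uniform start positions; both strands.
#'
#' @param genomes genome table to draw from.
#' @param mixture named numeric vector over genome labels, summing to 1:
#'   fraction of read mass per clade.
#' @param cfg a [sim_config()] (read length, error rate, read count).
#' @param sample_id sample name recorded in the read table.
#' @param seed RNG seed for this sample (defaults to `cfg$seed`).
#' @param genome_ids optional subset of genomes to draw from.
#' @return list with `reads` (tibble `sample_id`, `read_id`, `sequence`,
#'   `quality`) and `truth` (requested mixture, realized per-genome read
#'   counts, source coordinates).
#' @export
simulate_reads <- function(genomes, mixture, cfg, sample_id = "sample",
                           seed = cfg$seed, genome_ids = NULL) {
  if (abs(sum(mixture) - 1) > 1e-8) abort("mixture fractions must sum to 1")
  if (!all(names(mixture) %in% unique(genomes$label)))
    abort("mixture names must be genome labels")
  if (!is.null(genome_ids))
    genomes <- filter(genomes, .data$genome_id %in% genome_ids)
  gseq <- genomes |>
    group_by(.data$genome_id, .data$label) |>
    summarise(sequence = paste(.data$sequence, collapse = ""), .groups = "drop") |>
    mutate(len = nchar(.data$sequence))
  gseq <- gseq |>
    group_by(.data$label) |>
    mutate(w = (mixture[.data$label[1]] %||% 0) * .data$len / sum(.data$len)) |>
    ungroup()
  gseq$w[is.na(gseq$w)] <- 0
  if (all(gseq$w == 0)) abort("mixture assigns no mass to any genome present")
  with_seed(seed, {
    sim <- sim_reads_cpp(gseq$sequence, gseq$w, cfg$n_reads, cfg$read_length,
                         cfg$error_rate)
    reads <- tibble(
      sample_id = sample_id,
      read_id = sprintf("%s_r%07d", sample_id, seq_len(cfg$n_reads)),
      sequence = sim$read,
      quality = NA_character_
    )
    src <- tibble(read_id = reads$read_id,
                  genome_id = gseq$genome_id[sim$genome],
                  label = gseq$label[sim$genome],
                  start = sim$start, reverse = sim$rev)
    realized <- src |> count(.data$label) |> mutate(fraction = .data$n / sum(.data$n))
    list(reads = reads,
         truth = list(mixture = mixture, realized = realized, source = src))
  })
}
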