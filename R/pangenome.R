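#' Build a gene-cluster presence/absence matrix across genomes
#'
#' Greedy length-sorted clustering: genes are sorted by decreasing length
#' (ties broken by sequence, so the result is independent of genome order);
#' each gene joins the first existing cluster whose representative (the
#' founding, longest gene) it matches at `identity_threshold` or more over at
#' least `coverage_threshold` of the shorter sequence, else it founds a new
#' cluster. Identity is matches / alignment columns of a k-mer seeded banded
#' local alignment.
#'
#' @param genomes genome table (see [genome_table()]), at least two genomes.
#' @param identity_threshold,coverage_threshold clustering thresholds in
#'   (0, 1].
#' @param k seed k-mer length for the aligner.
#' @param band half-width of the alignment band around the seeded diagonal.
#' @param scoring alignment scores
#'   (`match`, `mismatch`, `gap_open`, `gap_ext`).
#' @return a `pangenome` object: binary presence matrix (clusters x
#'   genomes), cluster representatives, genome labels.
#' @export
build_pangenome <- function(genomes, identity_threshold = 0.95,
                            coverage_threshold = 0.80, k = 15, band = 32,
                            scoring = c(match = 1, mismatch = -1,
                                        gap_open = 2, gap_ext = 1)) {
  genomes <- genome_table(genomes)
  gids <- unique(genomes$genome_id)
  if (length(gids) < 2) abort("need at least 2 genomes")
  if (identity_threshold <= 0 || identity_threshold > 1 ||
      coverage_threshold <= 0 || coverage_threshold > 1)
    abort("thresholds must lie in (0, 1]")
  n_genes <- genomes |> count(.data$genome_id)
  # genome_table already rejects empty sequences; guard against zero genes
  empty <- setdiff(gids, n_genes$genome_id)
  if (length(empty) > 0)
    abort(sprintf("genome %s has an empty gene list", empty[1]))

  ord <- order(-nchar(genomes$sequence), genomes$sequence)
  res <- greedy_cluster_cpp(genomes$sequence[ord],
                            identity_threshold, coverage_threshold,
                            k, band, 8L,
                            scoring[["match"]], scoring[["mismatch"]],
                            scoring[["gap_open"]], scoring[["gap_ext"]])
  n_cl <- length(res$rep_gene)
  cluster_of <- integer(nrow(genomes))
  cluster_of[ord] <- res$assignment
  cluster_ids <- sprintf("CL%05d", seq_len(n_cl))

  presence <- matrix(0L, nrow = n_cl, ncol = length(gids),
                     dimnames = list(cluster_ids, gids))
  idx <- cbind(cluster_of, match(genomes$genome_id, gids))
  presence[idx] <- 1L

  clusters <- tibble(
    cluster_id = cluster_ids,
    representative = genomes$sequence[ord][res$rep_gene],
    length = nchar(genomes$sequence[ord][res$rep_gene]),
    n_genomes = as.integer(rowSums(presence))
  )
  labels <- genomes |> distinct(.data$genome_id, .data$label)
  structure(list(presence = presence, clusters = clusters, genomes = labels,
                 assignment = tibble(genome_id = genomes$genome_id,
                                     gene_id = genomes$gene_id,
                                     cluster_id = cluster_ids[cluster_of]),
                 params = list(identity_threshold = identity_threshold,
                               coverage_threshold = coverage_threshold,
                               k = k, band = band, scoring = scoring)),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat(sprintf("<pangenome> %d gene clusters x %d genomes (%s)\n",
              nrow(x$presence), ncol(x$presence),
              paste(sprintf("%s: %d", names(table(x$genomes$label)),
                            table(x$genomes$label)), collapse = ", ")))
  invisible(x)
}

#' @describeIn build_pangenome long tibble of the presence/absence matrix.
#' @param x a `pangenome` object.
#' @param ... unused.
#' @export
tidy.pangenome <- function(x, ...) {
  as_tibble(as.data.frame.table(x$presence, stringsAsFactors = FALSE)) |>
    setNames(c("cluster_id", "genome_id", "present")) |>
    mutate(present = as.integer(.data$present)) |>
    left_join(x$genomes, by = "genome_id")
}

#' @describeIn build_pangenome one-row summary (cluster counts, core size).
#' @export
glance.pangenome <- function(x, ...) {
  tibble(n_clusters = nrow(x$presence), n_genomes = ncol(x$presence),
         n_core = sum(rowSums(x$presence) == ncol(x$presence)),
         n_singleton = sum(rowSums(x$presence) == 1))
}

#' Flag mis-annotated genomes from presence/absence profiles
#'
#' Genomes are partitioned into two groups by average-linkage hierarchical
#' clustering on the Jaccard distance between their gene-cluster
#' presence/absence profiles. A genome is flagged when its subspecies label
#' disagrees with the majority label of its group (ties in the majority flag
#' every labeled genome of the group: ambiguity surfaces rather than hides).
#' Flagged genomes are reported, never dropped - exclusion is the caller's
#' explicit choice (see `excluded_genomes` in [select_candidates()]).
#'
#' @param pangenome a [build_pangenome()] result with >= 2 labeled genomes
#'   per subspecies.
#' @return an `outlier_report`: per-genome group assignment, silhouette-like
#'   score, and the flagged genome ids.
#' @export
detect_mislabeled <- function(pangenome) {
  stopifnot(inherits(pangenome, "pangenome"))
  labs <- pangenome$genomes
  clades <- setdiff(unique(labs$label), "unknown")
  cnt <- table(labs$label[labs$label != "unknown"])
  if (length(clades) < 2 || any(cnt < 2))
    abort("need at least 2 labeled genomes per subspecies")
  d <- vegan::vegdist(t(pangenome$presence), method = "jaccard", binary = TRUE)
  if (all(d == 0)) abort("no cluster structure: all presence/absence profiles identical")
  hc <- hclust(d, method = "average")
  grp <- cutree(hc, k = 2)
  sil <- cluster::silhouette(grp, d)
  report <- labs |>
    mutate(group = grp[.data$genome_id],
           silhouette = sil[match(.data$genome_id, labs$genome_id), "sil_width"])
  maj <- report |>
    filter(.data$label != "unknown") |>
    count(.data$group, .data$label) |>
    group_by(.data$group) |>
    summarise(majority_label = if (sum(.data$n == max(.data$n)) > 1) NA_character_
              else .data$label[which.max(.data$n)],
              .groups = "drop")
  report <- report |>
    left_join(maj, by = "group") |>
    mutate(flagged = .data$label != "unknown" &
             (is.na(.data$majority_label) | .data$label != .data$majority_label))
  structure(list(assignment = report,
                 flagged = report$genome_id[report$flagged]),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d genome(s) flagged as mis-annotated",
              length(x$flagged)))
  if (length(x$flagged) > 0)
    cat(":", paste(x$flagged, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @describeIn detect_mislabeled per-genome tibble of the report.
#' @param x an `outlier_report`.
#' @param ... unused.
#' @export
tidy.outlier_report <- function(x, ...) x$assignment
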