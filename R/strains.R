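#' Per-sample consensus sequences over marker genes
#'
#' For each sample, reads assigned to markers are piled up per marker
#' position; a position is called when depth reaches `min_depth` and the top
#' allele frequency reaches `majority`, else it is `N`. Markers with fewer
#' than `min_callable` callable positions in a sample are dropped for that
#' sample, and a sample is kept only when at least `min_marker_count`
#' markers survive (default 50, scaled down to half the database when the
#' database holds fewer than 50 markers). Consensus rows are the
#' concatenation of all used markers in database order; markers missing in a
#' sample contribute `N`s.
#'
#' @param hits mapping table from [map_reads()], one or more samples
#'   (distinguished by `sample_id`).
#' @param reads the read table(s) the hits were produced from.
#' @param db marker database used for mapping; subset it first to restrict
#'   the analysis to one clade's markers.
#' @param min_depth minimum pileup depth for a call.
#' @param majority minimum top-allele frequency for a call.
#' @param min_marker_count markers a sample must cover to be kept.
#' @param min_callable minimum callable fraction for a marker in a sample.
#' @return a `strain_alignment`: consensus character matrix (samples x
#'   concatenated positions), per-site depth, markers used, samples kept.
#' @export
build_consensus <- function(hits, reads, db, min_depth = 3, majority = 0.8,
                            min_marker_count = NULL, min_callable = 0.5) {
  min_marker_count <- min_marker_count %||%
    (if (nrow(db) >= 50) 50L else ceiling(nrow(db) / 2))
  samples <- sort(unique(hits$sample_id))
  total_len <- sum(db$length)
  base_rows <- c("A", "C", "G", "T", "N")
  marker_of_site <- rep(db$marker_id, db$length)

  per_sample <- lapply(samples, function(sid) {
    h <- hits |> filter(.data$sample_id == sid, !is.na(.data$marker_id),
                        .data$marker_id %in% db$marker_id)
    r <- reads |> filter(.data$sample_id == sid)
    seq_of <- r$sequence[match(h$read_id, r$read_id)]
    if (any(is.na(seq_of))) abort("hits reference reads absent from the read table")
    counts <- pileup_cpp(seq_of, seq_along(seq_of),
                         match(h$marker_id, db$marker_id),
                         h$marker_start, h$read_start, h$aligned_bases,
                         h$reverse, db$length)
    depth <- colSums(counts)
    top <- apply(counts[1:4, , drop = FALSE], 2, max)
    top_base <- base_rows[max.col(t(counts[1:4, , drop = FALSE]),
                                  ties.method = "first")]
    call <- ifelse(depth >= min_depth & top / pmax(depth, 1) >= majority,
                   top_base, "N")
    # 50/50 allele splits must not be called: max.col alone would pick one
    tied <- colSums(counts[1:4, , drop = FALSE] == rep(top, each = 4)) > 1 & top > 0
    call[tied & top / pmax(depth, 1) < 1] <- "N"
    callable <- tapply(call != "N", marker_of_site, mean)[db$marker_id]
    ok_markers <- db$marker_id[!is.na(callable) & callable >= min_callable]
    call[!marker_of_site %in% ok_markers] <- "N"
    list(call = call, depth = depth, markers = ok_markers)
  })
  names(per_sample) <- samples

  kept <- samples[vapply(per_sample, function(x)
    length(x$markers), 1L) >= min_marker_count]
  if (length(kept) == 0) {
    warn("no sample covers enough markers; empty strain alignment")
    return(structure(list(samples = character(),
                          markers_used = db[0, c("marker_id", "length")],
                          consensus = matrix("N", 0, 0), depth = matrix(0, 0, 0),
                          marker_of_site = character()),
                     class = "strain_alignment"))
  }
  used <- db$marker_id[db$marker_id %in%
                         unique(unlist(lapply(per_sample[kept], `[[`, "markers")))]
  site_keep <- marker_of_site %in% used
  consensus <- do.call(rbind, lapply(per_sample[kept], function(x) x$call[site_keep]))
  depth <- do.call(rbind, lapply(per_sample[kept], function(x) x$depth[site_keep]))
  rownames(consensus) <- rownames(depth) <- kept
  structure(list(samples = kept,
                 markers_used = db[db$marker_id %in% used, c("marker_id", "length")],
                 consensus = consensus, depth = depth,
                 marker_of_site = marker_of_site[site_keep]),
            class = "strain_alignment")
}

#' @export
print.strain_alignment <- function(x, ...) {
  cat(sprintf("<strain_alignment> %d sample(s) x %d sites over %d marker(s)\n",
              length(x$samples), ncol(x$consensus), nrow(x$markers_used)))
  invisible(x)
}

#' @describeIn build_consensus long tibble of consensus calls.
#' @param x a `strain_alignment`.
#' @param ... unused.
#' @export
tidy.strain_alignment <- function(x, ...) {
  if (length(x$samples) == 0)
    return(tibble(sample_id = character(), marker_id = character(),
                  site = integer(), call = character(), depth = double()))
  tibble(sample_id = rep(x$samples, each = ncol(x$consensus)),
         marker_id = rep(x$marker_of_site, length(x$samples)),
         site = rep(seq_len(ncol(x$consensus)), length(x$samples)),
         call = as.vector(t(x$consensus)),
         depth = as.vector(t(x$depth)))
}

#' Pairwise SNP distances between strain consensus sequences
#'
#' Distance between two samples is mismatches divided by the number of sites
#' where both have a non-`N`, non-gap call. Pairs with zero comparable sites
#' get `NA`, never 0.
#'
#' @param aln a `strain_alignment` with at least 2 samples.
#' @return symmetric matrix of normalized SNP distances (class `snp_dist`),
#'   with the comparable-site counts in attribute `n_sites`.
#' @export
pairwise_distances <- function(aln) {
  stopifnot(inherits(aln, "strain_alignment"))
  n <- length(aln$samples)
  if (n < 2) abort("need at least 2 samples for pairwise distances")
  valid <- aln$consensus %in% c("A", "C", "G", "T")
  dim(valid) <- dim(aln$consensus)
  d <- matrix(0, n, n, dimnames = list(aln$samples, aln$samples))
  ns <- matrix(0L, n, n, dimnames = list(aln$samples, aln$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- valid[i, ] & valid[j, ]
      ns[i, j] <- ns[j, i] <- sum(both)
      d[i, j] <- d[j, i] <- if (sum(both) == 0) NA_real_ else
        mean(aln$consensus[i, both] != aln$consensus[j, both])
    }
  }
  structure(d, n_sites = ns, class = c("snp_dist", "matrix", "array"))
}

#' @describeIn pairwise_distances long tibble of pairwise distances.
#' @param x a `snp_dist` matrix.
#' @param ... unused.
#' @export
tidy.snp_dist <- function(x, ...) {
  m <- unclass(x)
  ns <- attr(x, "n_sites")
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  tibble(sample_a = rownames(m)[pairs[, 1]],
         sample_b = colnames(m)[pairs[, 2]],
         distance = m[pairs],
         n_sites = as.integer(ns[pairs]))
}

#' Neighbor-joining tree from a SNP distance matrix
#'
#' Standard neighbor joining with deterministic input order (samples sorted
#' lexicographically) and non-negative branch lengths: a negative NJ edge is
#' clamped to zero and its deficit transferred to the sibling edge, leaving
#' all path lengths between leaves unchanged up to the clamp.
#'
#' @param dm `snp_dist` or plain symmetric matrix with >= 3 samples.
#' @return the tree as a newick string (class `submarker_tree`); the `ape`
#'   `phylo` object is attached as attribute `phylo`.
#' @export
nj_tree <- function(dm) {
  m <- as.matrix(unclass(dm))
  if (nrow(m) < 3) abort("need at least 3 samples for a tree")
  if (any(is.na(m)))
    abort("distance matrix has missing entries: drop incomplete samples first")
  ord <- order(rownames(m))
  m <- m[ord, ord]
  tr <- ape::nj(m)
  # clamp negative branch lengths, moving the deficit to the sibling edge
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs) > 0)
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    tr$edge.length[e] <- 0
  }
  nwk <- ape::write.tree(tr)
  structure(nwk, phylo = tr, class = "submarker_tree")
}

#' @export
print.submarker_tree <- function(x, ...) {
  cat(unclass(x), "\n")
  invisible(x)
}
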