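#' Map metagenomic reads to a marker database
#'
#' k-mer seeded, ungapped mapping of each read (both orientations) against
#' every marker. A read is assigned to at most one marker, the one with the
#' best identity; an exact best-identity tie between distinct markers of the
#' winning clade discards the read as ambiguous. Reads whose best hits in
#' the two clades are indistinguishable (identity difference below
#' `ambig_delta`) are counted toward the species-level pool rather than
#' either clade - the source of the "unclassified" remainder in
#' [estimate_abundance()]. Unmapped reads are counted, never errors.
#'
#' @param reads read table (`read_id`, `sequence`, optionally `sample_id`)
#'   or a character vector of sequences.
#' @param db marker database from [build_marker_db()] / [read_marker_db()].
#' @param min_identity minimum identity for a hit to count.
#' @param min_aligned minimum aligned bases for a hit to count.
#' @param k,probe_step mapper seed length and probe stride along the read.
#' @param ambig_delta identity margin below which the two clades'
#'   best hits are considered indistinguishable.
#' @return tibble of hits: `sample_id`, `read_id`, `marker_id` (`NA` for
#'   species-pool reads), `clade` (a clade name or `"species"`), `identity`,
#'   `aligned_bases`, `marker_start`, `read_start` (0-based), `reverse`.
#'   Attributes `n_reads`, `n_unmapped`, `n_dropped_ties` carry the read
#'   accounting.
#' @export
map_reads <- function(reads, db, min_identity = 0.95, min_aligned = 40,
                      k = 17, probe_step = 8, ambig_delta = 0.01) {
  if (nrow(db) == 0) abort("marker database is empty")
  if (is.character(reads))
    reads <- tibble(sample_id = "sample",
                    read_id = sprintf("r%07d", seq_along(reads)),
                    sequence = reads)
  if (!"sample_id" %in% names(reads)) reads$sample_id <- "sample"
  clades <- sort(unique(db$clade))
  clade_code <- match(db$clade, clades)
  if (length(clades) == 1) clade_code[] <- 1L
  res <- map_reads_cpp(reads$sequence, db$sequence, clade_code,
                       as.integer(k), as.integer(probe_step),
                       min_identity, as.integer(min_aligned), ambig_delta)
  keep <- res$status %in% c(1L, 2L)
  hits <- tibble(
    sample_id = reads$sample_id[keep],
    read_id = reads$read_id[keep],
    read_idx = which(keep),
    marker_id = ifelse(is.na(res$marker[keep]), NA_character_,
                       db$marker_id[res$marker[keep]]),
    clade = ifelse(res$status[keep] == 2L, "species",
                   db$clade[res$marker[keep]]),
    identity = res$identity[keep],
    aligned_bases = res$aligned[keep],
    marker_start = res$mstart[keep],
    read_start = res$read_lo[keep],
    reverse = res$rev[keep]
  )
  attr(hits, "n_reads") <- nrow(reads)
  attr(hits, "n_unmapped") <- sum(res$status == 0L)
  attr(hits, "n_dropped_ties") <- sum(res$status == 3L)
  hits
}

#' Estimate per-clade relative abundance from marker hits
#'
#' Per-marker depth is aligned bases on the marker divided by marker length.
#' A clade's abundance score is the truncated mean of its markers' depths
#' (top and bottom 10% discarded; with fewer than 10 markers the minimum and
#' maximum; with fewer than 3, a plain mean). The species-level score is
#' computed the same way from the ambiguous pool spread uniformly over all
#' markers, and the unclassified remainder is
#' `max(0, species score - sum of clade scores)`. The mapped share of the
#' sample (in reads) is split across `{clade A, clade B, unclassified}`
#' proportionally to these scores; `"other"` is the unmapped remainder, so
#' entries always sum to 100.
#'
#' @param hits tibble from [map_reads()].
#' @param db the marker database used for mapping.
#' @param read_count_total total reads in the sample (defaults to the
#'   `n_reads` attribute of `hits`).
#' @param trim trimming fraction of the truncated mean.
#' @param sample_id sample name for the profile (defaults from `hits`).
#' @param detection_threshold floor (percent) for the `detected` flag.
#' @return an abundance profile tibble: `sample_id`, `clade`,
#'   `relative_abundance` (percent, summing to 100), `detected`.
#' @export
estimate_abundance <- function(hits, db, read_count_total = NULL,
                               trim = 0.10, sample_id = NULL,
                               detection_threshold = 0.5) {
  read_count_total <- read_count_total %||% attr(hits, "n_reads")
  if (is.null(read_count_total))
    abort("read_count_total not given and hits carry no n_reads attribute")
  sample_id <- sample_id %||%
    (if (nrow(hits) > 0) hits$sample_id[1] else "sample")
  clades <- sort(unique(db$clade))
  entries <- c(setNames(rep(0, length(clades)), clades),
               unclassified = 0, other = 100)
  if (read_count_total == 0 || nrow(hits) == 0) {
    if (read_count_total == 0) entries["other"] <- 100
    prof <- tibble(sample_id = sample_id, clade = names(entries),
                   relative_abundance = unname(entries))
    prof$relative_abundance[] <- c(rep(0, length(clades) + 1), 100)
  } else {
    assigned <- filter(hits, .data$clade != "species")
    depth_by_marker <- assigned |>
      count(.data$marker_id, wt = .data$aligned_bases, name = "bases")
    per_marker <- db |>
      left_join(depth_by_marker, by = "marker_id") |>
      mutate(bases = coalesce(.data$bases, 0),
             depth = .data$bases / .data$length)
    clade_score <- per_marker |>
      group_by(.data$clade) |>
      summarise(score = truncated_mean(.data$depth, trim), .groups = "drop")
    scores <- setNames(rep(0, length(clades)), clades)
    scores[clade_score$clade] <- clade_score$score
    # ambiguous pool spread uniformly over all markers, aggregated the same way
    pool_bases <- sum(hits$aligned_bases[hits$clade == "species"])
    species_score <- truncated_mean(
      rep(pool_bases / sum(db$length), nrow(db)), trim)
    unclassified <- max(0, species_score - sum(scores))
    mapped_pct <- 100 * nrow(hits) / read_count_total
    weights <- c(scores, unclassified = unclassified)
    if (sum(weights) > 0) {
      alloc <- mapped_pct * weights / sum(weights)
    } else {
      alloc <- weights
      alloc["unclassified"] <- mapped_pct
    }
    entries[names(alloc)] <- alloc
    entries["other"] <- 100 - mapped_pct
    prof <- tibble(sample_id = sample_id, clade = names(entries),
                   relative_abundance = unname(entries))
  }
  prof$detected <- prof$relative_abundance >= detection_threshold
  class(prof) <- c("abundance_profile", class(tibble()))
  prof
}

#' Is a clade detectable in a profile?
#'
#' A clade counts as detected when its relative abundance reaches the
#' detectability floor (default 0.5%, boundary inclusive).
#'
#' @param profile abundance profile tibble.
#' @param clade clade name present in the profile.
#' @param threshold detection floor in percent.
#' @return logical.
#' @export
is_detected <- function(profile, clade, threshold = 0.5) {
  if (!clade %in% profile$clade)
    abort(sprintf("clade %s not in profile", clade))
  profile$relative_abundance[profile$clade == clade] >= threshold
}

#' Within-species subspecies shares
#'
#' Renormalizes an abundance profile over the species' own entries (the two
#' subspecies and, optionally, the unclassified remainder), dropping the
#' non-target `"other"` mass. This is the scale on which computational
#' estimates are compared with qPCR ratios.
#'
#' @param profile abundance profile tibble (one or more samples).
#' @param include_unclassified keep the unclassified remainder in the
#'   denominator.
#' @return tibble `sample_id`, `clade`, `share` (fractions summing to 1 per
#'   sample; `NA` when the species is entirely absent).
#' @export
clade_shares <- function(profile, include_unclassified = TRUE) {
  drop <- if (include_unclassified) "other" else c("other", "unclassified")
  profile |>
    filter(!.data$clade %in% drop) |>
    group_by(.data$sample_id) |>
    mutate(share = if (sum(.data$relative_abundance) > 0)
      .data$relative_abundance / sum(.data$relative_abundance)
      else NA_real_) |>
    ungroup() |>
    select("sample_id", "clade", "share")
}
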