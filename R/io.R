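#' Normalize DNA sequence text
#'
#' Upper-cases sequences and maps IUPAC ambiguity codes other than `N` to `N`.
#' The number of replaced bases is reported with a message so silent data
#' degradation cannot occur.
#'
#' @param x character vector of DNA sequences.
#' @param quiet suppress the replacement message.
#' @return character vector over the alphabet `A`, `C`, `G`, `T`, `N`.
#' @export
normalize_dna <- function(x, quiet = FALSE) {
  x <- toupper(x)
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", x), function(m) sum(m > 0), 1L))
  if (n_bad > 0) {
    x <- gsub("[^ACGTN]", "N", x)
    if (!quiet) inform(sprintf("mapped %d ambiguous base(s) to N", n_bad))
  }
  x
}

fasta_to_tibble <- function(path, quiet = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  tibble(gene_id = ids, sequence = unname(normalize_dna(as.character(set), quiet = quiet)))
}

#' Read a directory of annotated genomes
#'
#' Each genome is one multi-FASTA of gene sequences; `labels_path` is a
#' two-column TSV (`genome_id`, `label`) assigning genomes to subspecies.
#' Genomes absent from the labels file are labeled `"unknown"`; labels naming
#' a genome with no FASTA raise a warning and no record is fabricated.
#'
#' @param path directory containing one FASTA per genome (`.fa`, `.fasta`,
#'   `.fna`, optionally gzipped). The genome identifier is the file name
#'   without extension.
#' @param labels_path path to the labels TSV (no header). `NULL` labels
#'   every genome `"unknown"`.
#' @return a genome table: one row per gene with columns `genome_id`,
#'   `label`, `gene_id`, `sequence` (see [genome_table()]).
#' @export
read_genome_dir <- function(path, labels_path = NULL) {
  files <- list.files(path, pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                      full.names = TRUE)
  if (length(files) == 0) abort(sprintf("no FASTA files found in %s", path))
  ids <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(files))
  if (anyDuplicated(ids))
    abort(sprintf("duplicate genome_id: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  labels <- if (is.null(labels_path)) {
    tibble(genome_id = character(), label = character())
  } else {
    read_labels(labels_path)
  }
  missing <- setdiff(labels$genome_id, ids)
  if (length(missing) > 0)
    warn(sprintf("labels name genome(s) with no FASTA: %s",
                 paste(missing, collapse = ", ")))
  genes <- map2(files, ids, function(f, id) {
    tb <- fasta_to_tibble(f)
    if (anyDuplicated(tb$gene_id))
      abort(sprintf("duplicate gene_id in genome %s", id))
    mutate(tb, genome_id = id, .before = 1)
  })
  out <- bind_rows(genes) |>
    left_join(labels, by = "genome_id") |>
    mutate(label = coalesce(.data$label, "unknown")) |>
    select("genome_id", "label", "gene_id", "sequence")
  genome_table(out)
}

#' Read a genome-to-subspecies labels file
#'
#' @param path two-column TSV (`genome_id`, `label`), no header.
#' @return tibble with columns `genome_id`, `label`.
#' @export
read_labels <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, col.names = c("genome_id", "label"),
                   colClasses = "character", quote = "", comment.char = "")
  if (anyDuplicated(df$genome_id)) abort("duplicate genome_id in labels file")
  as_tibble(df)
}

#' Validate a genome table
#'
#' A genome table holds one row per annotated gene: `genome_id`, `label`
#' (a subspecies name or `"unknown"`), `gene_id`, `sequence`. Gene ids must
#' be unique within a genome, sequences non-empty, and each genome carries a
#' single label.
#'
#' @param x data frame with the four columns above.
#' @return the validated tibble.
#' @export
genome_table <- function(x) {
  x <- as_tibble(x)
  need <- c("genome_id", "label", "gene_id", "sequence")
  if (!all(need %in% names(x)))
    abort(paste("genome table needs columns:", paste(need, collapse = ", ")))
  if (any(nchar(x$sequence) == 0)) abort("empty gene sequence")
  dup <- x |> count(.data$genome_id, .data$gene_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0)
    abort(sprintf("duplicate gene_id within genome %s", dup$genome_id[1]))
  multi <- x |> distinct(.data$genome_id, .data$label) |> count(.data$genome_id) |>
    filter(.data$n > 1)
  if (nrow(multi) > 0)
    abort(sprintf("genome %s carries more than one label", multi$genome_id[1]))
  x
}

#' Write one genome's genes as FASTA
#'
#' @param genes tibble with `gene_id` and `sequence`.
#' @param path output FASTA path.
#' @export
write_gene_fasta <- function(genes, path) {
  set <- Biostrings::DNAStringSet(genes$sequence)
  names(set) <- genes$gene_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a genome table as a directory of FASTAs plus labels TSV
#'
#' @param genomes genome table (see [genome_table()]).
#' @param path output directory (created if needed).
#' @return `path`, invisibly. Writes `<genome_id>.fasta` per genome and
#'   `labels.tsv`.
#' @export
write_genome_dir <- function(genomes, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  genomes |>
    group_by(.data$genome_id) |>
    group_walk(function(g, key) {
      write_gene_fasta(g, file.path(path, paste0(key$genome_id, ".fasta")))
    })
  labs <- distinct(genomes, .data$genome_id, .data$label)
  write.table(labs, file.path(path, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- marker database --------------------------------------------------------

marker_provenance_cols <- c("cluster_id", "presence_fraction", "decoy_passed")

#' Write a marker database
#'
#' On-disk form: FASTA with structured headers
#' `>marker_id|clade=<name>|len=<int>` plus a sidecar TSV
#' (`<path>.tsv`) of per-marker provenance (source cluster, presence
#' fraction, decoy-filter verdict).
#'
#' @param db a marker database tibble from [build_marker_db()].
#' @param path output FASTA path; the sidecar is written to `<path>.tsv`.
#' @export
write_marker_db <- function(db, path) {
  if (nrow(db) == 0) abort("marker database is empty")
  headers <- sprintf("%s|clade=%s|len=%d", db$marker_id, db$clade, db$length)
  set <- Biostrings::DNAStringSet(db$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  side <- db |> select(any_of(c("marker_id", "clade", "length", marker_provenance_cols)))
  # full-precision numerics so write -> read round trips are lossless
  side <- mutate(side, across(where(is.double), ~ sprintf("%.17g", .x)))
  write.table(side, paste0(path, ".tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker database
#'
#' @param path FASTA written by [write_marker_db()]; the sidecar TSV is read
#'   from `<path>.tsv` when present.
#' @return marker database tibble; `read(write(db))` equals `db`.
#' @export
read_marker_db <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) abort(sprintf("empty marker FASTA: %s", path))
  m <- str_match(names(set), "^([^|]+)\\|clade=([^|]+)\\|len=(\\d+)$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0) {
    header_lines <- grep("^>", readLines(path))
    abort(sprintf("malformed marker header at line %d: >%s",
                  header_lines[bad[1]], names(set)[bad[1]]))
  }
  db <- tibble(marker_id = m[, 2], clade = m[, 3], length = as.integer(m[, 4]),
               sequence = normalize_dna(as.character(set), quiet = TRUE))
  if (any(db$length != nchar(db$sequence)))
    abort("marker header len= disagrees with sequence length")
  if (anyDuplicated(db$marker_id)) abort("duplicate marker_id in marker FASTA")
  side_path <- paste0(path, ".tsv")
  if (file.exists(side_path)) {
    side <- as_tibble(read.table(side_path, sep = "\t", header = TRUE,
                                 quote = "", comment.char = ""))
    db <- left_join(db, select(side, -any_of(c("clade", "length"))), by = "marker_id")
  }
  new_marker_db(db)
}

new_marker_db <- function(x) {
  class(x) <- c("marker_db", class(tibble()))
  x
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf("<marker_db> %d markers (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(table(x$clade)), table(x$clade)),
                    collapse = ", ")))
  NextMethod()
}

# ---- reads ------------------------------------------------------------------

#' Read sequencing reads (FASTA or FASTQ)
#'
#' @param path reads file; format inferred from extension (`.fq`/`.fastq`
#'   vs `.fa`/`.fasta`), gzip allowed.
#' @param sample_id sample identifier attached to the table; defaults to the
#'   file name without extension.
#' @return tibble with columns `sample_id`, `read_id`, `sequence`, `quality`
#'   (`NA` for FASTA input).
#' @export
read_reads <- function(path, sample_id = NULL) {
  is_fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  sample_id <- sample_id %||% sub("\\.(fq|fastq|fa|fasta)(\\.gz)?$", "",
                                  basename(path), ignore.case = TRUE)
  if (is_fastq) {
    set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(set)$qualities)
  } else {
    set <- Biostrings::readDNAStringSet(path)
    qual <- rep(NA_character_, length(set))
  }
  if (length(set) == 0) abort(sprintf("no reads in %s", path))
  out <- tibble(sample_id = sample_id,
                read_id = sub("\\s.*$", "", names(set)),
                sequence = unname(normalize_dna(as.character(set), quiet = TRUE)),
                quality = unname(qual))
  bad <- !is.na(out$quality) & nchar(out$quality) != nchar(out$sequence)
  if (any(bad)) abort(sprintf("quality length mismatch for read %s",
                              out$read_id[which(bad)[1]]))
  out
}

#' Write reads as FASTQ (or FASTA)
#'
#' @param reads tibble with `read_id`, `sequence`, optional `quality`.
#' @param path output path; FASTQ unless it ends in `.fa`/`.fasta`.
#' @export
write_reads <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$read_id
  if (grepl("\\.(fa|fasta)(\\.gz)?$", path, ignore.case = TRUE)) {
    Biostrings::writeXStringSet(set, path)
  } else {
    qual <- reads$quality
    if (is.null(qual) || all(is.na(qual)))
      qual <- vapply(nchar(reads$sequence), function(n)
        paste(rep("I", n), collapse = ""), "")
    Biostrings::writeXStringSet(set, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual))
  }
  invisible(path)
}

# ---- abundance profiles -----------------------------------------------------

#' Write an abundance profile TSV
#'
#' One sample per file, MetaPhlAn-style: a `#clade<TAB>relative_abundance`
#' header, percentages on a 0-100 scale.
#'
#' @param profile abundance profile tibble for a single sample.
#' @param path output TSV path.
#' @export
write_abundance <- function(profile, path) {
  if (length(unique(profile$sample_id)) != 1)
    abort("write_abundance() writes one sample per file")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sample_id: %s", profile$sample_id[1]), con)
  writeLines("#clade\trelative_abundance", con)
  writeLines(sprintf("%s\t%.10g", profile$clade, profile$relative_abundance), con)
  invisible(path)
}

#' Read an abundance profile TSV
#'
#' @param path file written by [write_abundance()].
#' @return abundance profile tibble (`sample_id`, `clade`,
#'   `relative_abundance`, `detected`).
#' @param detection_threshold floor (percent) used to re-derive the
#'   `detected` flag.
#' @export
read_abundance <- function(path, detection_threshold = 0.5) {
  lines <- readLines(path)
  sid <- sub("^#sample_id: ", "", lines[1])
  body <- lines[!startsWith(lines, "#")]
  parts <- str_split_fixed(body, "\t", 2)
  out <- tibble(sample_id = sid, clade = parts[, 1],
                relative_abundance = as.numeric(parts[, 2]))
  out$detected <- out$relative_abundance >= detection_threshold
  class(out) <- c("abundance_profile", class(tibble()))
  out
}

# ---- qPCR Ct tables ---------------------------------------------------------

#' Read a qPCR Ct table
#'
#' @param path TSV with header columns `sample_id`, `target`, `ct`,
#'   `replicate`.
#' @return validated tibble (positive Ct values, >= 1 replicate per
#'   sample/target pair).
#' @export
read_ct_table <- function(path) {
  df <- as_tibble(read.table(path, sep = "\t", header = TRUE,
                             quote = "", comment.char = ""))
  need <- c("sample_id", "target", "ct", "replicate")
  if (!all(need %in% names(df)))
    abort(paste("Ct table needs columns:", paste(need, collapse = ", ")))
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) abort("Ct values must be positive")
  df
}

#' Write a distance matrix as TSV
#'
#' @param dm symmetric numeric matrix with sample dimnames.
#' @param path output path.
#' @export
write_distance_matrix <- function(dm, path) {
  write.table(as.matrix(dm), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a distance matrix TSV
#'
#' @param path file written by [write_distance_matrix()].
#' @return symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE))
  storage.mode(m) <- "double"
  m
}
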