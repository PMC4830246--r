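#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @return A tibble with columns `id` (full header line) and `seq`.
#'   Record order is preserved.
#' @details Duplicated ids are an error: downstream joins key on the read or
#'   reference identifier.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_mm("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- names(set)
  if (anyNA(ids) || any(ids == "")) stop_mm("FASTA records must carry an id: ", path)
  if (anyDuplicated(ids)) {
    stop_mm("duplicated FASTA id(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tibble(id = ids, seq = as.character(set, use.names = FALSE))
}

#' Write sequences to a FASTA file
#'
#' @param x Data frame with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  check_cols(x, c("id", "seq"), "x")
  set <- Biostrings::BStringSet(x$seq)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Strict 4-line-per-record FASTQ reader. Any structural violation (record
#' count not a multiple of four, missing `@`/`+` markers, quality string whose
#' length differs from the sequence) is an error naming the offending line.
#'
#' @param path Path to a FASTQ file (plain or gzip-compressed).
#' @return A tibble with columns `id`, `seq`, `qual` in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_mm("file not found: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop_mm("malformed FASTQ (", path, "): ", n,
            " lines is not a multiple of 4 (after line ", n, ")")
  }
  if (n == 0L) return(tibble(id = character(), seq = character(), qual = character()))
  hdr <- lines[seq(1L, n, by = 4L)]
  seq <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  qual <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0) {
    stop_mm("malformed FASTQ (", path, "): expected '@' at line ", 4L * (bad[1] - 1L) + 1L)
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0) {
    stop_mm("malformed FASTQ (", path, "): expected '+' at line ", 4L * (bad[1] - 1L) + 3L)
  }
  bad <- which(nchar(qual) != nchar(seq))
  if (length(bad) > 0) {
    stop_mm("malformed FASTQ (", path, "): quality length differs from sequence length at line ",
            4L * (bad[1] - 1L) + 4L)
  }
  ids <- sub("^@", "", hdr)
  if (anyDuplicated(ids)) {
    stop_mm("duplicated FASTQ id(s): ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tibble(id = ids, seq = seq, qual = qual)
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param x Data frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  check_cols(x, c("id", "seq", "qual"), "x")
  if (any(nchar(x$qual) != nchar(x$seq))) {
    stop_mm("quality strings must match sequence lengths")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("@", x$id, "\n", x$seq, "\n+\n", x$qual), con, sep = "\n")
  invisible(path)
}

tab_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a 12-column tabular alignment file
#'
#' Parses the tab-separated 12-column alignment layout (BLAST/DIAMOND
#' `-outfmt 6`): query id, subject id, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, E-value, bit
#' score. The dialect is fixed: rows with any other number of columns are
#' rejected with the offending line number, as are non-numeric numeric fields.
#'
#' @param path Path to the tabular file.
#' @return A tibble with the canonical column names
#'   `qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore`, rows in file order.
#' @export
read_alignment_tab <- function(path) {
  if (!file.exists(path)) stop_mm("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- tibble(qseqid = character(), sseqid = character(), pident = double(),
                  length = integer(), mismatch = integer(), gapopen = integer(),
                  qstart = integer(), qend = integer(), sstart = integer(),
                  send = integer(), evalue = double(), bitscore = double())
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad) > 0) {
    stop_mm("malformed alignment table (", path, "): ", nf[bad[1]],
            " columns instead of 12 at line ", bad[1])
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(col, what, integerish = FALSE) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      stop_mm("malformed alignment table (", path, "): non-numeric ", what,
              " at line ", which(is.na(v))[1])
    }
    if (integerish) as.integer(v) else v
  }
  out <- tibble(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = num(3, "pident"), length = num(4, "length", TRUE),
    mismatch = num(5, "mismatch", TRUE), gapopen = num(6, "gapopen", TRUE),
    qstart = num(7, "qstart", TRUE), qend = num(8, "qend", TRUE),
    sstart = num(9, "sstart", TRUE), send = num(10, "send", TRUE),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore")
  )
  validate_hits(out, path)
  out
}

validate_hits <- function(hits, what = "hits") {
  if (any(hits$qstart > hits$qend)) {
    stop_mm("invalid alignment table (", what, "): qstart > qend")
  }
  if (any(hits$bitscore <= 0)) {
    stop_mm("invalid alignment table (", what, "): bit score must be positive")
  }
  if (any(hits$evalue < 0)) {
    stop_mm("invalid alignment table (", what, "): negative E-value")
  }
  invisible(hits)
}

#' Write hits as a 12-column tabular alignment file
#'
#' Only the 12 canonical columns are written, in the `-outfmt 6` order, so the
#' output round-trips through [read_alignment_tab()] and interoperates with
#' external aligners.
#'
#' @param hits Data frame containing at least the 12 canonical columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_tab <- function(hits, path) {
  check_cols(hits, tab_cols, "hits")
  df <- as.data.frame(hits[, tab_cols])
  df$evalue <- formatC(df$evalue, format = "g", digits = 6)
  df$pident <- formatC(df$pident, format = "f", digits = 3)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read or write a taxonomy table
#'
#' A taxonomy table is a TSV with header `taxid, parent, rank, name`; the root
#' is its own parent. [read_taxonomy()] validates the tree structure via
#' [taxonomy_table()].
#'
#' @param path Path to the TSV file.
#' @return A validated taxonomy tibble.
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    taxid = readr::col_character(), parent = readr::col_character(),
    rank = readr::col_character(), name = readr::col_character()
  ))
  taxonomy_table(df)
}

#' @rdname read_taxonomy
#' @param taxonomy A validated taxonomy tibble.
#' @export
write_taxonomy <- function(taxonomy, path) {
  check_cols(taxonomy, c("taxid", "parent", "rank", "name"), "taxonomy")
  readr::write_tsv(taxonomy, path)
  invisible(path)
}

#' Read a per-family BSR cutoff table
#'
#' TSV with header `family, dataset, cutoff`. Cutoffs are numbers in `[0, 1]`
#' or the sentinel `"manual"` for families screened by manual inspection.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `family`, `dataset`, `cutoff` (numeric,
#'   `NA` for manual) and `manual` (logical).
#' @export
read_cutoffs <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    family = readr::col_character(), dataset = readr::col_character(),
    cutoff = readr::col_character()
  ))
  manual <- tolower(df$cutoff) == "manual"
  val <- suppressWarnings(as.numeric(df$cutoff))
  if (any(!manual & is.na(val))) {
    stop_mm("cutoff values must be numeric or 'manual' (", path, ")")
  }
  if (any(!manual & (val < 0 | val > 1))) {
    stop_mm("numeric cutoffs must lie in [0, 1] (", path, ")")
  }
  tibble(family = df$family, dataset = df$dataset,
         cutoff = ifelse(manual, NA_real_, val), manual = manual)
}

#' Pipeline configuration
#'
#' Bundles the tunable screening parameters with their defaults: the
#' translated-search E-value cutoff (1e-6), the quality-trim limit (an error
#' probability of 0.05), the post-trim length filter (>= 100 bp) and the
#' ambiguity filter (at most 2 N bases), plus the per-family BSR cutoff table
#' and the RNG seed.
#'
#' @param evalue_cutoff Maximum E-value for a translated hit.
#' @param quality_limit Error-probability limit for quality trimming, in (0, 1).
#' @param min_length Minimum retained read length in bp (inclusive).
#' @param max_ambiguous Maximum number of ambiguous (N) bases per read.
#' @param cutoffs Per-family cutoff tibble as returned by [read_cutoffs()] or
#'   [table1_cutoffs()].
#' @param seed Integer seed for stochastic steps.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(evalue_cutoff = 1e-6, quality_limit = 0.05,
                            min_length = 100L, max_ambiguous = 2L,
                            cutoffs = table1_cutoffs(), seed = 1L) {
  check_number(evalue_cutoff, "evalue_cutoff", lower = 0, allow_lower = FALSE)
  check_number(quality_limit, "quality_limit", lower = 0, upper = 1,
               allow_lower = FALSE, allow_upper = FALSE)
  check_number(min_length, "min_length", lower = 1)
  check_number(max_ambiguous, "max_ambiguous", lower = 0)
  check_cols(cutoffs, c("family", "dataset", "cutoff", "manual"), "cutoffs")
  bad <- !cutoffs$manual & (is.na(cutoffs$cutoff) | cutoffs$cutoff < 0 | cutoffs$cutoff > 1)
  if (any(bad)) stop_mm("numeric cutoffs must lie in [0, 1]")
  structure(list(evalue_cutoff = evalue_cutoff, quality_limit = quality_limit,
                 min_length = as.integer(min_length),
                 max_ambiguous = as.integer(max_ambiguous),
                 cutoffs = cutoffs, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys: `evalue_cutoff`, `quality_limit`, `min_length`,
#' `max_ambiguous`, `seed`, and `cutoffs` (a list of `{family, dataset,
#' cutoff}` entries where `cutoff` is a number or `"manual"`). Missing keys
#' fall back to the [pipeline_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cutoffs <- if (is.null(y$cutoffs)) table1_cutoffs() else {
    rows <- lapply(y$cutoffs, function(e) {
      manual <- identical(tolower(as.character(e$cutoff)), "manual")
      tibble(family = as.character(e$family),
             dataset = as.character(e$dataset %||% "default"),
             cutoff = if (manual) NA_real_ else as.numeric(e$cutoff),
             manual = manual)
    })
    bind_rows(rows)
  }
  pipeline_config(
    evalue_cutoff = y$evalue_cutoff %||% 1e-6,
    quality_limit = y$quality_limit %||% 0.05,
    min_length = y$min_length %||% 100L,
    max_ambiguous = y$max_ambiguous %||% 2L,
    cutoffs = cutoffs,
    seed = y$seed %||% 1L
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  evalue_cutoff: ", format(x$evalue_cutoff), "\n", sep = "")
  cat("  quality_limit: ", x$quality_limit, "\n", sep = "")
  cat("  min_length:    ", x$min_length, " bp\n", sep = "")
  cat("  max_ambiguous: ", x$max_ambiguous, "\n", sep = "")
  cat("  families:      ", length(unique(x$cutoffs$family)), "\n", sep = "")
  invisible(x)
}

#' Write an abundance table as TSV
#'
#' @param x Abundance tibble from [abundance_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
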