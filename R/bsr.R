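#' Packaged per-family BSR cutoff defaults
#'
#' The packaged default cutoff table for the two-database BLAST-score-ratio
#' filter, one row per (marker family, dataset). Datasets `PA2` and `PA5` are
#' a suboxic-zone and an anoxic-core oxygen-minimum-zone metagenome; the
#' sentinel `manual` marks families whose hits were screened by manual
#' inspection rather than a numeric threshold (reference sets with few
#' targets). The `nxrA` values are the second-round cutoffs used to separate
#' nxrA from narG; `hdh` is resolved by read mapping, not by a cutoff.
#'
#' @return A tibble with columns `family`, `dataset`, `cutoff` (numeric or
#'   `NA` for manual families) and `manual`.
#' @export
table1_cutoffs <- function() {
  long <- function(family, pa2, pa5) {
    tibble(family = family, dataset = c("PA2", "PA5"), cutoff = c(pa2, pa5))
  }
  out <- bind_rows(
    long("nifH", NA, NA),
    long("amoA", NA, NA),
    long("hao", NA, 0.75),
    long("nxrA", 0.85, 0.85),
    long("narG", 0.5, 0.5),
    long("nirK", 0.55, 0.55),
    long("nirS", NA, 0.6),
    long("norB_norZ", 0.8, 0.8),
    long("nosZ", 0.8, 0.75),
    long("nrfA", NA, NA),
    long("hzsA", NA, 0.75),
    long("mcrA", NA, NA),
    long("mmoX", NA, NA),
    long("pmoA", NA, NA),
    long("mpnS", NA, NA),
    long("phnGHI", NA, NA)
  )
  mutate(out, manual = is.na(.data$cutoff))
}

#' Compute the two-database BLAST score ratio per read
#'
#' The core false-positive filter statistic: for each read with a hit to the
#' curated marker database, the ratio of its best custom-database bit score
#' to its best background-database (NR-proxy) bit score. Reads with no
#' background hit have low similarity to anything outside the curated set and
#' are kept as true positives (sentinel ratio `NA`, `no_background = TRUE`).
#'
#' @param custom_best Best-per-read custom-database hits ([best_hits()]);
#'   must contain `qseqid`, `bitscore` and (if available) `family`.
#' @param background_best Best-per-read background-database hits, or an empty
#'   tibble. Only reads present in `custom_best` are considered.
#' @return A tibble of undecided BSR records: `read_id`, `family`,
#'   `custom_score`, `background_score` (`NA` if absent), `ratio` (`NA` if no
#'   background hit) and `no_background`.
#' @export
compute_bsr <- function(custom_best, background_best) {
  check_cols(custom_best, c("qseqid", "bitscore"), "custom_best")
  check_cols(background_best, c("qseqid", "bitscore"), "background_best")
  if (anyDuplicated(custom_best$qseqid)) {
    stop_mm("`custom_best` must have one row per read (use best_hits())")
  }
  if (anyDuplicated(background_best$qseqid)) {
    stop_mm("`background_best` must have one row per read (use best_hits())")
  }
  if (any(custom_best$bitscore <= 0) || any(background_best$bitscore <= 0)) {
    stop_mm("bit scores must be positive")
  }
  fam <- if ("family" %in% names(custom_best)) custom_best$family else NA_character_
  out <- tibble(read_id = custom_best$qseqid,
                family = fam,
                custom_score = custom_best$bitscore)
  out <- left_join(out,
                   select(background_best, read_id = "qseqid", background_score = "bitscore"),
                   by = "read_id")
  mutate(out,
         ratio = .data$custom_score / .data$background_score,
         no_background = is.na(.data$background_score))
}

#' Apply per-family cutoffs to BSR records
#'
#' A record is `kept` when its ratio is at least the family cutoff (boundary
#' inclusive) or when it has no background hit; otherwise `discarded`.
#' Families with the `manual` sentinel get `flagged_manual` and are meant to
#' be exported for review ([export_manual_review()]); a `keep_list` of read
#' ids can replay a completed manual review reproducibly.
#'
#' @param records BSR records from [compute_bsr()].
#' @param cutoffs Cutoff tibble (`family`, `cutoff`, `manual`, optionally
#'   `dataset`), e.g. [table1_cutoffs()] or [read_cutoffs()].
#' @param dataset If `cutoffs` has a `dataset` column, which dataset's
#'   cutoffs to use.
#' @param keep_list Optional character vector of read ids confirmed as true
#'   positives for manually screened families.
#' @return `records` with columns `cutoff` and `decision`
#'   (`kept` / `discarded` / `flagged_manual`).
#' @export
apply_cutoff <- function(records, cutoffs, dataset = NULL, keep_list = NULL) {
  check_cols(records, c("read_id", "family", "custom_score", "ratio", "no_background"),
             "records")
  check_cols(cutoffs, c("family", "cutoff"), "cutoffs")
  if (!"manual" %in% names(cutoffs)) cutoffs$manual <- is.na(cutoffs$cutoff)
  if ("dataset" %in% names(cutoffs) && !is.null(dataset)) {
    cutoffs <- filter(cutoffs, .data$dataset == !!dataset)
  }
  cutoffs <- distinct(cutoffs, .data$family, .keep_all = TRUE)
  missing <- setdiff(unique(records$family), cutoffs$family)
  if (length(missing) > 0) {
    stop_mm("no cutoff for family(ies): ", paste(missing, collapse = ", "))
  }
  # re-deciding already-decided records is allowed: refresh those columns
  records <- records[, setdiff(names(records), c("cutoff", "manual", "decision"))]
  out <- left_join(records, select(cutoffs, "family", "cutoff", "manual"),
                   by = "family")
  out <- mutate(out, decision = dplyr::case_when(
    .data$manual & !is.null(keep_list) & .data$read_id %in% keep_list ~ "kept",
    .data$manual ~ "flagged_manual",
    .data$no_background ~ "kept",
    .data$ratio >= .data$cutoff ~ "kept",
    TRUE ~ "discarded"
  ))
  select(out, -"manual")
}

#' Export records flagged for manual review
#'
#' Writes the `flagged_manual` records as a TSV so that the manual
#' true-positive review becomes a reproducible data artifact: the reviewed
#' ids can be fed back through `apply_cutoff(keep_list = ...)`.
#'
#' @param records Decided records from [apply_cutoff()].
#' @param path Output TSV path.
#' @return The flagged subset, invisibly.
#' @export
export_manual_review <- function(records, path) {
  check_cols(records, c("read_id", "family", "decision"), "records")
  flagged <- filter(records, .data$decision == "flagged_manual")
  readr::write_tsv(flagged, path)
  invisible(flagged)
}

#' Scatter and histogram data for BSR diagnostics
#'
#' Returns plotting-ready data mirroring the screening diagnostics: one
#' scatter point per read with a custom-database hit (background score on x,
#' custom score on y; reads without a background hit sit on the y-axis
#' margin at x = 0) and the per-read ratio values for the histogram.
#'
#' @param records BSR records ([compute_bsr()] or [apply_cutoff()]).
#' @return A list with tibbles `points` (`read_id`, `family`, `x`, `y`,
#'   `no_background`, and `decision` if present) and `ratios` (`read_id`,
#'   `family`, `ratio`; background-absent reads excluded).
#' @export
bsr_scatter_data <- function(records) {
  check_cols(records, c("read_id", "family", "custom_score", "ratio", "no_background"),
             "records")
  if (nrow(records) == 0) stop_mm("no BSR records to plot")
  pts <- tibble(read_id = records$read_id, family = records$family,
                x = ifelse(records$no_background, 0, records$background_score),
                y = records$custom_score,
                no_background = records$no_background)
  if ("decision" %in% names(records)) pts$decision <- records$decision
  list(points = pts,
       ratios = filter(select(records, "read_id", "family", "ratio"),
                       !is.na(.data$ratio)))
}

#' Plot the BSR scatter diagnostic
#'
#' @param records BSR records, ideally after [apply_cutoff()].
#' @param cutoffs Optional cutoff tibble to draw the `y = cutoff * x`
#'   decision line per family.
#' @return A ggplot object (one facet per family).
#' @export
plot_bsr_scatter <- function(records, cutoffs = NULL) {
  d <- bsr_scatter_data(records)
  p <- ggplot2::ggplot(d$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = if ("decision" %in% names(d$points))
      .data$decision else .data$no_background),
      alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~family, scales = "free") +
    ggplot2::labs(x = "background (NR-proxy) bit score",
                  y = "custom database bit score", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(cutoffs)) {
    cl <- distinct(filter(cutoffs, .data$family %in% d$points$family, !is.na(.data$cutoff)),
                   .data$family, .keep_all = TRUE)
    if (nrow(cl) > 0) {
      p <- p + ggplot2::geom_abline(data = cl,
                                    ggplot2::aes(slope = .data$cutoff, intercept = 0),
                                    linetype = "dashed")
    }
  }
  p
}

#' Plot the BSR ratio histogram
#'
#' @inheritParams plot_bsr_scatter
#' @param binwidth Histogram bin width on the ratio axis.
#' @return A ggplot object (one facet per family).
#' @export
plot_bsr_histogram <- function(records, cutoffs = NULL, binwidth = 0.05) {
  d <- bsr_scatter_data(records)
  p <- ggplot2::ggplot(d$ratios, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::facet_wrap(~family, scales = "free_y") +
    ggplot2::labs(x = "bit score ratio (custom / background)", y = "reads") +
    ggplot2::theme_minimal()
  if (!is.null(cutoffs)) {
    cl <- distinct(filter(cutoffs, .data$family %in% d$ratios$family, !is.na(.data$cutoff)),
                   .data$family, .keep_all = TRUE)
    if (nrow(cl) > 0) {
      p <- p + ggplot2::geom_vline(data = cl, ggplot2::aes(xintercept = .data$cutoff),
                                   linetype = "dashed")
    }
  }
  p
}
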