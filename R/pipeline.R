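#' Run the marker-gene screen on one read set
#'
#' Chains the core screening stages: quality trim and length/ambiguity
#' filter, translated search against the custom marker database and the
#' background (NR-proxy) database, per-read best-hit reduction, BSR
#' computation, and per-family cutoff decisions.
#'
#' @param reads Tibble `id`, `seq` and, if trimming is enabled, `qual`.
#' @param custom Custom marker reference tibble (`id`, `seq`, `family`).
#' @param background Background reference tibble (`id`, `seq`).
#' @param cutoffs Cutoff tibble (see [apply_cutoff()]).
#' @param dataset Dataset label selecting cutoff rows and labelling output.
#' @param config A [pipeline_config()] (E-value cutoff, trim and filter
#'   settings).
#' @param trim Whether to quality-trim first (requires `qual`).
#' @param keep_list Optional read ids confirming manually screened families.
#' @param ... Further arguments to [search_reads()].
#' @return A `marker_screen` object: a list with `records` (decided BSR
#'   records), `kept` (kept reads with their family), `hits_custom`,
#'   `hits_background` (full hit tables), `reads_screened` (post-QC reads)
#'   and `dataset`.
#' @export
run_marker_screen <- function(reads, custom, background, cutoffs,
                              dataset = NULL, config = pipeline_config(),
                              trim = "qual" %in% names(reads),
                              keep_list = NULL, ...) {
  if (!inherits(config, "pipeline_config")) stop_mm("`config` must be a pipeline_config")
  if (isTRUE(trim)) {
    reads <- trim_reads(reads, config$quality_limit)
  }
  reads <- filter_reads(reads, config$min_length, config$max_ambiguous)
  hits_c <- search_reads(reads, custom, evalue_cutoff = config$evalue_cutoff, ...)
  hits_b <- search_reads(reads, background, evalue_cutoff = config$evalue_cutoff, ...)
  best_c <- best_hits(hits_c)
  best_b <- best_hits(hits_b)
  records <- compute_bsr(best_c, best_b)
  records <- apply_cutoff(records, cutoffs, dataset = dataset,
                          keep_list = keep_list)
  if (!is.null(dataset)) records$dataset <- dataset
  kept <- records |>
    filter(.data$decision == "kept") |>
    select("read_id", "family", "ratio")
  structure(list(records = records, kept = kept, hits_custom = hits_c,
                 hits_background = hits_b, reads_screened = reads,
                 dataset = dataset),
            class = "marker_screen")
}

#' @export
print.marker_screen <- function(x, ...) {
  cat("<marker_screen", if (!is.null(x$dataset)) paste0(" [", x$dataset, "]"),
      ">\n", sep = "")
  cat("  reads screened: ", nrow(x$reads_screened), "\n", sep = "")
  cat("  reads with custom hit: ", nrow(x$records), "\n", sep = "")
  tab <- table(x$records$decision)
  cat("  decisions: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Tidy the decided BSR records of a marker screen
#'
#' @param x A `marker_screen` object.
#' @param ... Unused.
#' @return The decided records tibble (one row per read with a custom hit).
#' @export
tidy.marker_screen <- function(x, ...) {
  as_tibble(x$records)
}

#' One-row summary of a marker screen
#'
#' @param x A `marker_screen` object.
#' @param ... Unused.
#' @return A tibble with read, hit, and per-decision counts.
#' @export
glance.marker_screen <- function(x, ...) {
  tibble(dataset = x$dataset %||% NA_character_,
         n_reads = nrow(x$reads_screened),
         n_with_hit = nrow(x$records),
         n_kept = sum(x$records$decision == "kept"),
         n_discarded = sum(x$records$decision == "discarded"),
         n_flagged_manual = sum(x$records$decision == "flagged_manual"),
         n_families = length(unique(x$records$family)))
}

#' @rdname plot_bsr_scatter
#' @param object A `marker_screen` object.
#' @param ... Unused.
#' @export
autoplot.marker_screen <- function(object, ...) {
  plot_bsr_scatter(object$records)
}

#' Per-family kept-read counts of a marker screen
#'
#' Convenience bridge from a screen to [abundance_table()].
#'
#' @param screen A `marker_screen` object.
#' @return Tibble `family`, `dataset`, `raw_count`.
#' @export
kept_counts <- function(screen) {
  if (!inherits(screen, "marker_screen")) stop_mm("`screen` must be a marker_screen")
  screen$kept |>
    group_by(.data$family) |>
    summarise(raw_count = n(), .groups = "drop") |>
    mutate(dataset = screen$dataset %||% "all")
}
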