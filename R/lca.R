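#' Validate a taxonomy table
#'
#' @param df Data frame with columns `taxid`, `parent`, `rank`, `name`.
#'   Exactly one root (its own parent) is required; every parent must exist;
#'   cycles are rejected.
#' @return The validated tibble (invisibly classed `taxonomy_tbl`).
#' @export
taxonomy_table <- function(df) {
  check_cols(df, c("taxid", "parent", "rank", "name"), "df")
  df <- as_tibble(df)
  df$taxid <- as.character(df$taxid)
  df$parent <- as.character(df$parent)
  if (anyDuplicated(df$taxid)) stop_mm("duplicated taxid(s)")
  roots <- df$taxid[df$taxid == df$parent]
  if (length(roots) != 1L) {
    stop_mm("taxonomy must have exactly one root (parent == taxid); found ",
            length(roots))
  }
  if (!all(df$parent %in% df$taxid)) {
    stop_mm("parent id(s) missing from taxonomy: ",
            paste(head(setdiff(df$parent, df$taxid), 5), collapse = ", "))
  }
  # cycle check: every node must reach the root
  parent <- setNames(df$parent, df$taxid)
  for (t in df$taxid) {
    seen <- character()
    cur <- t
    while (parent[[cur]] != cur) {
      if (cur %in% seen) stop_mm("taxonomy contains a cycle through ", cur)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  class(df) <- c("taxonomy_tbl", class(df))
  df
}

# ancestor path from node to root, node first
ancestor_path <- function(taxid, parent) {
  path <- character()
  cur <- taxid
  repeat {
    path <- c(path, cur)
    nxt <- parent[[cur]]
    if (nxt == cur) break
    cur <- nxt
  }
  path
}

lca_of_nodes <- function(nodes, parent) {
  nodes <- unique(nodes)
  path <- ancestor_path(nodes[1], parent)
  for (nd in nodes[-1]) {
    anc <- ancestor_path(nd, parent)
    path <- path[path %in% anc]
  }
  path[1]
}

#' Assign reads to taxonomy by a lowest-common-ancestor rule
#'
#' MEGAN-style LCA assignment: for each read, candidate hits are those with a
#' bit score over `min_score_fraction` of the read's top bit score (strict by
#' default), truncated to the `max_hits` best (ties broken by subject id);
#' the read is assigned to the lowest common ancestor of the candidates'
#' taxa. The defaults follow the rule "taxonomy of maximum 5 hits with over
#' 90% score from the top hit". The top hit always qualifies, so every read
#' with a hit gets an assignment.
#'
#' @param hits Hit tibble (`qseqid`, `sseqid`, `bitscore`).
#' @param taxonomy A [taxonomy_table()].
#' @param subject_taxa Tibble `sseqid`, `taxid` mapping every subject to a
#'   taxonomy node; a subject without a mapping is an error.
#' @param max_hits Maximum number of candidate hits (default 5, counting the
#'   top hit).
#' @param min_score_fraction Fraction of the top bit score a candidate must
#'   exceed (default 0.9).
#' @param inclusive If `TRUE`, candidates at exactly the score threshold also
#'   qualify (default `FALSE`: strictly over the threshold).
#' @return A tibble `read_id`, `taxid`, `name`, `rank`.
#' @export
assign_lca <- function(hits, taxonomy, subject_taxa, max_hits = 5L,
                       min_score_fraction = 0.9, inclusive = FALSE) {
  check_cols(hits, c("qseqid", "sseqid", "bitscore"), "hits")
  check_cols(subject_taxa, c("sseqid", "taxid"), "subject_taxa")
  if (!inherits(taxonomy, "taxonomy_tbl")) taxonomy <- taxonomy_table(taxonomy)
  check_number(max_hits, "max_hits", lower = 1)
  check_number(min_score_fraction, "min_score_fraction", lower = 0, upper = 1,
               allow_lower = FALSE)
  check_flag(inclusive, "inclusive")
  if (nrow(hits) == 0) {
    return(tibble(read_id = character(), taxid = character(),
                  name = character(), rank = character()))
  }
  unknown <- setdiff(unique(hits$sseqid), subject_taxa$sseqid)
  if (length(unknown) > 0) {
    stop_mm("subject(s) without taxonomy mapping: ",
            paste(head(unknown, 5), collapse = ", "))
  }
  taxmap <- setNames(as.character(subject_taxa$taxid), subject_taxa$sseqid)
  bad <- setdiff(unique(unname(taxmap[unique(hits$sseqid)])), taxonomy$taxid)
  if (length(bad) > 0) {
    stop_mm("taxid(s) missing from taxonomy: ", paste(head(bad, 5), collapse = ", "))
  }
  parent <- setNames(taxonomy$parent, taxonomy$taxid)

  per_read <- split(hits[, c("sseqid", "bitscore")], hits$qseqid)
  res <- vapply(per_read, function(h) {
    top <- max(h$bitscore)
    thr <- min_score_fraction * top
    cand <- if (inclusive) h[h$bitscore >= thr, ] else h[h$bitscore > thr, ]
    cand <- cand[order(-cand$bitscore, cand$sseqid), ]
    cand <- head(cand, max_hits)
    lca_of_nodes(unname(taxmap[cand$sseqid]), parent)
  }, character(1))
  out <- tibble(read_id = names(res), taxid = unname(res))
  left_join(out, select(taxonomy, "taxid", "name", "rank"), by = "taxid")
}

#' Summarise taxonomic assignments as per-group read fractions
#'
#' Groups below `min_fraction` of the reads in every dataset are collapsed
#' into `"other"`, mirroring the "more than 1% of the total community in at
#' least one of the two datasets" reporting rule. Fractions (including
#' `other`) sum to 1 per dataset.
#'
#' @param assignments Tibble with a `group` column (e.g. the `name` from
#'   [assign_lca()]) and optionally a `dataset` column; one row per read.
#' @param min_fraction Reporting threshold (default 0.01).
#' @return A tibble `dataset`, `group`, `n_reads`, `fraction`.
#' @export
summarize_taxa <- function(assignments, min_fraction = 0.01) {
  check_cols(assignments, "group", "assignments")
  if (nrow(assignments) == 0) stop_mm("no assignments to summarise")
  check_number(min_fraction, "min_fraction", lower = 0, upper = 1)
  if (!"dataset" %in% names(assignments)) assignments$dataset <- "all"
  tab <- assignments |>
    group_by(.data$dataset, .data$group) |>
    summarise(n_reads = n(), .groups = "drop_last") |>
    mutate(fraction = .data$n_reads / sum(.data$n_reads)) |>
    ungroup()
  keep <- tab |>
    group_by(.data$group) |>
    summarise(keep = any(.data$fraction >= min_fraction), .groups = "drop")
  tab <- left_join(tab, keep, by = "group") |>
    mutate(group = if_else(.data$keep, .data$group, "other")) |>
    group_by(.data$dataset, .data$group) |>
    summarise(n_reads = sum(.data$n_reads), fraction = sum(.data$fraction),
              .groups = "drop") |>
    arrange(.data$dataset, desc(.data$fraction))
  tab
}
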