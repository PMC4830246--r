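#' Reconstruct a gene by iterative read mapping
#'
#' Reference-guided consensus reconstruction for marker genes too diverse to
#' assemble de novo: reads are mapped against a seed sequence (a related
#' reference gene), the per-column majority base over the read pileup
#' replaces the seed where covered, optionally the consensus is extended by
#' reads overhanging its ends, and the cycle repeats against the updated
#' consensus until the mapped read set repeats (cycle-safe) or `max_rounds`
#' is reached.
#'
#' @param reads Tibble `id`, `seq` of candidate reads.
#' @param seed_nt Non-empty seed nucleotide sequence.
#' @param params [mapping_params()]; per-gene operating values follow the packaged
#'   settings (50/50 for hdh; 80/50 for close nxrA; 30/50 with mismatch
#'   penalty 1 for divergent novel nxrA).
#' @param max_rounds Maximum mapping rounds (default 20).
#' @param extend Whether to extend the consensus beyond the seed boundaries
#'   using read overhangs (default `TRUE`).
#' @param min_overhang Minimum overhang length in bp to trigger extension
#'   (default 20).
#' @return A `gene_reconstruction` object: `consensus`, `mapped_ids`,
#'   `converged`, and a per-round `log` tibble (`round`, `n_mapped`,
#'   `consensus_length`).
#' @details Majority ties are broken in fixed base order A < C < G < T;
#'   columns with zero coverage keep the current consensus base. With no
#'   mappable reads the seed is returned unchanged and `converged` is TRUE.
#' @export
iterative_reconstruct <- function(reads, seed_nt, params = mapping_params(),
                                  max_rounds = 20L, extend = TRUE,
                                  min_overhang = 20L) {
  check_cols(reads, c("id", "seq"), "reads")
  if (!is.character(seed_nt) || length(seed_nt) != 1L || nchar(seed_nt) == 0) {
    stop_mm("`seed_nt` must be a non-empty sequence")
  }
  check_number(max_rounds, "max_rounds", lower = 1)
  consensus <- toupper(seed_nt)
  seen <- list()
  log <- list()
  mapped_ids <- character()
  converged <- FALSE
  for (round in seq_len(max_rounds)) {
    m <- map_reads(reads, tibble(id = "consensus", seq = consensus), params)
    mm <- filter(m, .data$mapped)
    mapped_ids <- sort(mm$read_id)
    log[[round]] <- tibble(round = round, n_mapped = length(mapped_ids),
                           consensus_length = nchar(consensus))
    key <- paste(mapped_ids, collapse = ",")
    if (any(vapply(seen, identical, logical(1), key))) {
      converged <- TRUE
      break
    }
    seen <- c(seen, key)
    if (nrow(mm) == 0) {
      converged <- TRUE
      break
    }
    # full read sequence in mapped orientation, for overhang extension
    full <- reads$seq[match(mm$read_id, reads$id)]
    neg <- mm$strand == -1L
    if (any(neg)) full[neg] <- revcomp_chr(full[neg])
    mm$read_full <- full
    consensus <- update_consensus(consensus, mm, extend, min_overhang)
  }
  structure(list(consensus = consensus, mapped_ids = mapped_ids,
                 converged = converged, rounds = length(log),
                 log = bind_rows(log)),
            class = "gene_reconstruction")
}

# majority-vote consensus over the pileup of mapped reads, with optional
# end extension from overhanging reads
update_consensus <- function(consensus, mapped, extend, min_overhang) {
  n <- nchar(consensus)
  base_levels <- c("A", "C", "G", "T")
  votes <- matrix(0L, nrow = 4, ncol = n, dimnames = list(base_levels, NULL))
  left_over <- character()
  right_over <- character()
  for (i in seq_len(nrow(mapped))) {
    qa <- strsplit(mapped$qaln[i], "")[[1]]
    sa <- strsplit(mapped$saln[i], "")[[1]]
    pos <- mapped$sstart[i]
    for (k in seq_along(sa)) {
      if (sa[k] == "-") next         # insertion in read: no reference column
      b <- qa[k]
      if (b %in% base_levels) votes[b, pos] <- votes[b, pos] + 1L
      pos <- pos + 1L
    }
    # overhangs: unaligned read sequence beyond the consensus ends
    read_seq <- mapped$read_full[i]
    if (mapped$sstart[i] == 1L && mapped$qstart[i] > 1L) {
      left_over <- c(left_over, substr(read_seq, 1L, mapped$qstart[i] - 1L))
    }
    if (mapped$send[i] == n && mapped$qend[i] < nchar(read_seq)) {
      right_over <- c(right_over, substr(read_seq, mapped$qend[i] + 1L,
                                         nchar(read_seq)))
    }
  }
  old <- strsplit(consensus, "")[[1]]
  covered <- colSums(votes) > 0L
  winners <- base_levels[apply(votes, 2, which.max)]
  new <- ifelse(covered, winners, old)
  out <- paste(new, collapse = "")
  if (extend) {
    lext <- extension_from_overhangs(left_over, min_overhang, left = TRUE)
    rext <- extension_from_overhangs(right_over, min_overhang, left = FALSE)
    out <- paste0(lext, out, rext)
  }
  out
}

# column-wise majority over end-anchored overhang strings (>= min_overhang
# required to trigger; all contributing overhangs vote per column)
extension_from_overhangs <- function(overs, min_overhang, left) {
  overs <- overs[nchar(overs) > 0]
  if (length(overs) == 0 || max(nchar(overs)) < min_overhang) return("")
  width <- max(nchar(overs))
  base_levels <- c("A", "C", "G", "T")
  cols <- character(width)
  for (w in seq_len(width)) {
    # column w counted outward from the consensus end
    b <- vapply(overs, function(o) {
      n <- nchar(o)
      if (n < w) return(NA_character_)
      if (left) substr(o, n - w + 1L, n - w + 1L) else substr(o, w, w)
    }, character(1))
    b <- b[!is.na(b) & b %in% base_levels]
    if (length(b) == 0) return(paste(cols[seq_len(w - 1L)], collapse = ""))
    cols[w] <- base_levels[which.max(tabulate(match(b, base_levels), 4))]
  }
  ext <- paste(cols, collapse = "")
  if (left) paste(rev(strsplit(ext, "")[[1]]), collapse = "") else ext
}

#' @export
print.gene_reconstruction <- function(x, ...) {
  cat("<gene_reconstruction> ", nchar(x$consensus), " bp consensus, ",
      length(x$mapped_ids), " reads mapped, ", x$rounds, " round(s), ",
      if (x$converged) "converged" else "round limit reached", "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.marker_screen
#' @export
tidy.gene_reconstruction <- function(x, ...) x$log

#' @rdname glance.marker_screen
#' @export
glance.gene_reconstruction <- function(x, ...) {
  tibble(consensus_length = nchar(x$consensus),
         n_mapped = length(x$mapped_ids),
         rounds = x$rounds, converged = x$converged)
}
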