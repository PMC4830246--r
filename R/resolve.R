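#' Read-mapping parameters
#'
#' CLC-style mapping thresholds: local alignment with match +1, a linear
#' mismatch penalty and a linear per-base indel penalty; a read maps when its
#' best local alignment reaches at least `min_identity` percent identity over
#' an aligned span of at least `min_read_coverage` percent of the read
#' length. The defaults (penalty 2/3, 50% identity over 50% of the read) are
#' the thresholds used for the hao/hdh split and hdh reconstruction; the
#' nxrA reconstructions use 80/50 and, for divergent novel lineages, 30/50
#' with mismatch penalty 1.
#'
#' @param mismatch_penalty Positive integer mismatch penalty (default 2).
#' @param indel_penalty Positive integer per-base indel penalty (default 3).
#' @param min_identity Percent identity threshold in (0, 100] (default 50).
#' @param min_read_coverage Percent-of-read-length threshold in (0, 100]
#'   (default 50).
#' @return A `mapping_params` list.
#' @export
mapping_params <- function(mismatch_penalty = 2L, indel_penalty = 3L,
                           min_identity = 50, min_read_coverage = 50) {
  check_number(mismatch_penalty, "mismatch_penalty", lower = 1)
  check_number(indel_penalty, "indel_penalty", lower = 1)
  check_number(min_identity, "min_identity", lower = 0, upper = 100,
               allow_lower = FALSE)
  check_number(min_read_coverage, "min_read_coverage", lower = 0, upper = 100,
               allow_lower = FALSE)
  structure(list(mismatch_penalty = as.integer(mismatch_penalty),
                 indel_penalty = as.integer(indel_penalty),
                 min_identity = min_identity,
                 min_read_coverage = min_read_coverage),
            class = "mapping_params")
}

#' Map reads against nucleotide references
#'
#' Aligns each read (both strands) against every reference with a local
#' aligner under the [mapping_params()] scoring scheme and partitions the
#' reads into mapped and unmapped. The partition is exhaustive and exclusive.
#'
#' @param reads Tibble with columns `id`, `seq` (nucleotide).
#' @param reference_nt Tibble with columns `id`, `seq` (nucleotide), one row
#'   per reference; must be non-empty.
#' @param params A [mapping_params()] object.
#' @return A tibble with one row per read: `read_id`, `mapped`, `ref_id`,
#'   `strand`, `score`, `pident`, `coverage` (percent of read length in the
#'   aligned span), `qstart`, `qend` (on the read in mapped orientation),
#'   `sstart`, `send`, and the gapped alignment strings `qaln`, `saln`
#'   (read given in mapped orientation).
#' @export
map_reads <- function(reads, reference_nt, params = mapping_params()) {
  check_cols(reads, c("id", "seq"), "reads")
  check_cols(reference_nt, c("id", "seq"), "reference_nt")
  if (nrow(reference_nt) == 0) stop_mm("empty reference set")
  if (nrow(reads) == 0) {
    return(tibble(read_id = character(), mapped = logical(), ref_id = character(),
                  strand = integer(), score = integer(), pident = double(),
                  coverage = double(), qstart = integer(), qend = integer(),
                  sstart = integer(), send = integer(),
                  qaln = character(), saln = character()))
  }
  m <- cpp_nt_map(reads$seq, reference_nt$seq,
                  params$mismatch_penalty, params$indel_penalty)
  span <- m$qend - m$qstart + 1L
  pident <- ifelse(m$length > 0, 100 * m$matches / m$length, 0)
  coverage <- 100 * span / nchar(reads$seq)
  coverage[m$length == 0] <- 0
  tibble(read_id = reads$id,
         mapped = pident >= params$min_identity &
           coverage >= params$min_read_coverage,
         ref_id = reference_nt$id[m$ref],
         strand = m$strand, score = m$score,
         pident = round(pident, 3), coverage = round(coverage, 3),
         qstart = m$qstart, qend = m$qend,
         sstart = m$sstart, send = m$send,
         qaln = m$qaln, saln = m$saln)
}

#' Split hao from hdh reads by mapping against reference hdh genes
#'
#' hao (hydroxylamine oxidoreductase) and hdh (hydrazine dehydrogenase) are
#' close octaheme homologs screened as one family. Reads kept by the family
#' BSR are mapped against reference hdh nucleotide copies; mapped reads are
#' classified `hdh`, unmapped reads `hao`. The two classes partition the
#' input exactly.
#'
#' @param reads Tibble of BSR-kept reads (`id`, `seq`).
#' @param hdh_reference_nt Nucleotide reference copies of hdh (`id`, `seq`).
#' @param params Mapping thresholds; default 50% identity over 50% of the
#'   read with penalties 2/3.
#' @return A tibble `read_id`, `class` (`"hdh"` or `"hao"`) plus the
#'   [map_reads()] alignment columns.
#' @export
split_hao_hdh <- function(reads, hdh_reference_nt, params = mapping_params()) {
  m <- map_reads(reads, hdh_reference_nt, params)
  mutate(m, class = if_else(.data$mapped, "hdh", "hao"))
}

#' Split narG from nxrA reads with a second BSR round
#'
#' Nitrate reductase (narG) and nitrite oxidoreductase (nxrA) are homologous
#' molybdopterin oxidoreductases screened as one combined family. Kept reads
#' are re-searched against two nxrA subset databases (the
#' Nitrobacter/Nitrococcus/Nitrolancea-type and the
#' Nitrospira/Nitrospina/anammox-type lineages, or synthetic stand-ins); for
#' each read the ratio of its best subset bit score to its original
#' combined-database score is computed, and a ratio of at least `bsr_cutoff`
#' (default 0.85) against a subset assigns the read to that subset's nxrA
#' class. Reads exceeding the cutoff against both subsets go to the subset
#' with the higher ratio (an exact tie is flagged `ambiguous`); all other
#' reads are classified `narG`. The three classes partition the input.
#'
#' @param reads Tibble of BSR-kept combined-family reads (`id`, `seq`).
#' @param subset_a,subset_b Amino-acid reference tibbles (`id`, `seq`) for
#'   the two nxrA subsets.
#' @param original_scores Tibble `read_id`, `custom_score` with each read's
#'   first-round best custom-database bit score; every read must be present.
#' @param bsr_cutoff Second-round ratio cutoff (default 0.85; reported range
#'   0.85-0.95 is exposed through this parameter).
#' @param ... Passed to [search_reads()] (internal scorer options).
#' @return A tibble `read_id`, `class` (`"nxrA_A"`, `"nxrA_B"`, `"narG"` or
#'   `"ambiguous"`), `ratio_a`, `ratio_b`.
#' @export
split_narg_nxra <- function(reads, subset_a, subset_b, original_scores,
                            bsr_cutoff = 0.85, ...) {
  check_cols(reads, c("id", "seq"), "reads")
  check_cols(original_scores, c("read_id", "custom_score"), "original_scores")
  check_number(bsr_cutoff, "bsr_cutoff", lower = 0, upper = 1, allow_lower = FALSE)
  missing <- setdiff(reads$id, original_scores$read_id)
  if (length(missing) > 0) {
    stop_mm("missing original score for read(s): ",
            paste(head(missing, 5), collapse = ", "))
  }
  best_sub <- function(subset) {
    h <- best_hits(search_reads(reads, subset, ...))
    select(h, read_id = "qseqid", sub_score = "bitscore")
  }
  a <- rename(best_sub(subset_a), score_a = "sub_score")
  b <- rename(best_sub(subset_b), score_b = "sub_score")
  out <- tibble(read_id = reads$id)
  out <- left_join(out, a, by = "read_id")
  out <- left_join(out, b, by = "read_id")
  out <- left_join(out, select(original_scores, "read_id", "custom_score"),
                   by = "read_id")
  out <- mutate(out,
                ratio_a = .data$score_a / .data$custom_score,
                ratio_b = .data$score_b / .data$custom_score)
  ra <- ifelse(is.na(out$ratio_a), -Inf, out$ratio_a)
  rb <- ifelse(is.na(out$ratio_b), -Inf, out$ratio_b)
  class <- rep("narG", nrow(out))
  class[ra >= bsr_cutoff & ra > rb] <- "nxrA_A"
  class[rb >= bsr_cutoff & rb > ra] <- "nxrA_B"
  class[ra >= bsr_cutoff & rb >= bsr_cutoff & ra == rb] <- "ambiguous"
  out$class <- class
  select(out, "read_id", "class", "ratio_a", "ratio_b")
}
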