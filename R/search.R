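#' Translate a nucleotide sequence in all six reading frames
#'
#' Standard genetic code; codons containing an ambiguous base translate to
#' `X`; stop codons appear as `*`. Frames are labelled `1, 2, 3` on the given
#' strand and `-1, -2, -3` on the reverse complement (frame `-1` of a
#' sequence equals frame `1` of its reverse complement). Trailing bases that
#' do not fill a codon are dropped.
#'
#' @param seqs Character vector of nucleotide sequences over `{A,C,G,T,N}`.
#' @return A tibble with columns `seq_index`, `frame`, `peptide`, ordered by
#'   sequence then frame (`1, 2, 3, -1, -2, -3`).
#' @export
translate_six_frames <- function(seqs) {
  if (length(seqs) == 0) {
    return(tibble(seq_index = integer(), frame = integer(), peptide = character()))
  }
  fwd <- Biostrings::DNAStringSet(seqs)
  rev <- Biostrings::reverseComplement(fwd)
  w <- Biostrings::width(fwd)
  one_frame <- function(set, off) {
    wf <- pmax(0L, ((w - off) %/% 3L) * 3L)
    sub <- Biostrings::subseq(set, start = off + 1L, width = wf)
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "X"))
  }
  frames <- list(
    `1` = one_frame(fwd, 0L), `2` = one_frame(fwd, 1L), `3` = one_frame(fwd, 2L),
    `-1` = one_frame(rev, 0L), `-2` = one_frame(rev, 1L), `-3` = one_frame(rev, 2L)
  )
  out <- tibble(
    seq_index = rep(seq_along(seqs), times = 6L),
    frame = rep(c(1L, 2L, 3L, -1L, -2L, -3L), each = length(seqs)),
    peptide = unlist(frames, use.names = FALSE)
  )
  arrange(out, .data$seq_index, factor(.data$frame, levels = c(1L, 2L, 3L, -1L, -2L, -3L)))
}

#' Screen reads against an amino-acid reference set
#'
#' Six-frame translated local-alignment search of nucleotide reads against a
#' protein reference database, the in-package equivalent of a BLASTx screen.
#' The internal scorer runs Smith-Waterman with BLOSM62-free parameters:
#' BLOSUM62 substitution scores, affine gaps (open 11, extend 1), a shared
#' 4-mer prefilter, and Karlin-Altschul bit scores and E-values using
#' published gapped-BLOSUM62 constants (lambda = 0.267, K = 0.041). Exact
#' parity with NCBI BLAST E-values is not promised; downstream decisions
#' depend on score ratios and a permissive E-value cutoff. Alternatively,
#' `scorer = "external"` ingests a 12-column tabular file produced by an
#' external aligner for the same reads.
#'
#' @param reads Tibble with columns `id`, `seq`.
#' @param reference Tibble with columns `id`, `seq` (amino acid) and
#'   optionally `family`; the per-hit `family` column is carried through.
#' @param evalue_cutoff Maximum E-value; default 1e-6.
#' @param scorer `"internal"` (built-in Smith-Waterman) or `"external"`.
#' @param hits For `scorer = "external"`: a path to, or tibble from,
#'   [read_alignment_tab()].
#' @param min_query_coverage Minimum fraction of the read covered by the hit
#'   (on the nucleotide scale); default 0.5, mirroring the 50%-of-read
#'   mapping thresholds used elsewhere in the pipeline. Set to 0 to disable.
#' @param gap_open,gap_extension Affine gap parameters (internal scorer).
#' @param kmer_size,min_kmer_hits Prefilter: a reference is aligned against a
#'   read frame only if they share at least `min_kmer_hits` amino-acid
#'   k-mers. `min_kmer_hits = 0` disables the prefilter (all pairs aligned).
#' @param karlin_lambda,karlin_k Karlin-Altschul calibration constants.
#' @param min_frame_aa Frames shorter than this many residues are skipped.
#' @return A tibble of per-(read, subject) best HSPs passing the E-value and
#'   coverage filters, with the 12 canonical tabular columns plus `frame` and
#'   (when available) `family`. Query coordinates are 1-based nucleotide
#'   positions on the forward strand of the read (`qstart <= qend`); the
#'   aligned strand is carried by the sign of `frame`.
#' @seealso [best_hits()] to reduce to the single best hit per read.
#' @export
search_reads <- function(reads, reference, evalue_cutoff = 1e-6,
                         scorer = c("internal", "external"), hits = NULL,
                         min_query_coverage = 0.5,
                         gap_open = 11L, gap_extension = 1L,
                         kmer_size = 4L, min_kmer_hits = 2L,
                         karlin_lambda = 0.267, karlin_k = 0.041,
                         min_frame_aa = 15L) {
  scorer <- match.arg(scorer)
  check_cols(reads, c("id", "seq"), "reads")
  check_number(evalue_cutoff, "evalue_cutoff", lower = 0, allow_lower = FALSE)
  check_number(min_query_coverage, "min_query_coverage", lower = 0, upper = 1)
  if (scorer == "external") {
    if (is.null(hits)) stop_mm("external scorer requires `hits`")
    tab <- if (is.character(hits)) read_alignment_tab(hits) else {
      validate_hits(check_cols(hits, tab_cols, "hits"))
    }
    unknown <- setdiff(unique(tab$qseqid), reads$id)
    if (length(unknown) > 0) {
      stop_mm("external hits reference unknown read id(s): ",
              paste(head(unknown, 5), collapse = ", "))
    }
    tab <- left_join(tab, tibble(qseqid = reads$id, .read_len = nchar(reads$seq)),
                     by = "qseqid")
    tab <- filter(tab,
                  .data$evalue <= evalue_cutoff,
                  (abs(.data$qend - .data$qstart) + 1) / .data$.read_len >= min_query_coverage)
    tab <- select(tab, -".read_len")
    if (!"frame" %in% names(tab)) tab$frame <- NA_integer_
    if (!is.null(reference) && "family" %in% names(reference)) {
      tab <- left_join(tab, select(reference, sseqid = "id", "family"), by = "sseqid")
    }
    return(as_tibble(tab))
  }

  check_cols(reference, c("id", "seq"), "reference")
  if (nrow(reference) == 0) stop_mm("empty reference set")
  empty <- tibble(qseqid = character(), sseqid = character(), pident = double(),
                  length = integer(), mismatch = integer(), gapopen = integer(),
                  qstart = integer(), qend = integer(), sstart = integer(),
                  send = integer(), evalue = double(), bitscore = double(),
                  frame = integer(),
                  family = if ("family" %in% names(reference)) character() else NULL)
  if (nrow(reads) == 0) return(empty)

  frames <- translate_six_frames(reads$seq)
  raw <- if (min_kmer_hits == 0) {
    # prefilter disabled: brute-force all pairs through the pairwise scorer
    sw_all_pairs(frames, reference$seq, gap_open, gap_extension, min_frame_aa)
  } else {
    cpp_sw_search(frames$peptide, frames$seq_index - 1L, frames$frame,
                  reference$seq, as.integer(kmer_size),
                  as.integer(min_kmer_hits),
                  as.integer(gap_open), as.integer(gap_extension),
                  as.integer(min_frame_aa))
  }
  if (nrow(raw) == 0) return(empty)

  read_len <- nchar(reads$seq)[raw$read]
  frame_len <- nchar(frames$peptide)[raw$frame_pos]
  db_len <- sum(nchar(reference$seq))
  bits <- (karlin_lambda * raw$score - log(karlin_k)) / log(2)
  evalue <- frame_len * db_len * 2^(-bits)

  f <- raw$frame
  fa <- abs(f)
  nt_s <- 3L * (raw$qstart - 1L) + fa
  nt_e <- 3L * raw$qend + fa - 1L
  qstart <- ifelse(f > 0, nt_s, read_len - nt_e + 1L)
  qend <- ifelse(f > 0, nt_e, read_len - nt_s + 1L)

  out <- tibble(
    qseqid = reads$id[raw$read],
    sseqid = reference$id[raw$ref],
    pident = round(100 * raw$matches / raw$length, 3),
    length = raw$length,
    mismatch = raw$mismatches,
    gapopen = raw$gapopens,
    qstart = as.integer(qstart), qend = as.integer(qend),
    sstart = raw$sstart, send = raw$send,
    evalue = evalue, bitscore = round(bits, 1),
    frame = f,
    .read = raw$read
  )
  if ("family" %in% names(reference)) out$family <- reference$family[raw$ref]
  out <- filter(out,
                .data$evalue <= evalue_cutoff,
                (.data$qend - .data$qstart + 1) / nchar(reads$seq[.data$.read]) >= min_query_coverage)
  out <- arrange(out, .data$.read, desc(.data$bitscore), .data$evalue, .data$sseqid)
  select(out, -".read")
}

# brute-force fallback used when the prefilter is switched off (tests)
sw_all_pairs <- function(frames, ref_seqs, gap_open, gap_extension, min_frame_aa) {
  rows <- list()
  k <- 0L
  for (fp in seq_len(nrow(frames))) {
    pep <- frames$peptide[fp]
    if (nchar(pep) < min_frame_aa) next
    for (r in seq_along(ref_seqs)) {
      st <- cpp_sw_pair(pep, ref_seqs[r], as.integer(gap_open), as.integer(gap_extension))
      if (st$score > 0) {
        k <- k + 1L
        rows[[k]] <- tibble(read = frames$seq_index[fp], ref = r,
                            frame = frames$frame[fp], frame_pos = fp,
                            score = st$score, qstart = st$qstart, qend = st$qend,
                            sstart = st$sstart, send = st$send, length = st$length,
                            matches = st$matches, mismatches = st$mismatches,
                            gapopens = st$gapopens, gaps = st$gaps)
      }
    }
  }
  if (k == 0L) return(tibble(read = integer(0)))
  all <- bind_rows(rows)
  all <- arrange(all, .data$read, .data$ref, desc(.data$score), .data$frame_pos)
  distinct(all, .data$read, .data$ref, .keep_all = TRUE)
}

#' Reduce a hit table to the best hit per read
#'
#' The best hit is the one with the maximal bit score; ties are broken by
#' smaller E-value, then lexicographically by subject id.
#'
#' @param hits Hit tibble from [search_reads()] or [read_alignment_tab()].
#' @return One row per `qseqid`.
#' @export
best_hits <- function(hits) {
  check_cols(hits, c("qseqid", "bitscore", "evalue", "sseqid"), "hits")
  hits |>
    arrange(desc(.data$bitscore), .data$evalue, .data$sseqid) |>
    distinct(.data$qseqid, .keep_all = TRUE) |>
    arrange(.data$qseqid)
}
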