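#' Quality-trim reads (modified-Mott algorithm)
#'
#' End-trims each read the way CLC-style quality trimming does: every base is
#' scored `quality_limit - p` where `p = 10^(-Q/10)` is its Phred error
#' probability, and the retained region is the contiguous subsequence with the
#' maximal score sum. Bases better than the limit contribute positively, worse
#' bases negatively; a read whose bases are all worse than the limit trims to
#' empty. Ties are broken leftmost-first, then longest.
#'
#' @param reads Tibble with columns `id`, `seq`, `qual` (Phred+33).
#' @param quality_limit Error-probability limit in (0, 1); default 0.05.
#' @return The input tibble with `seq` and `qual` replaced by the trimmed
#'   region (possibly empty) and new columns `trim_start`, `trim_end`
#'   (1-based coordinates on the input read; 0/0 for an empty result).
#' @details Trimming is idempotent and always returns a contiguous substring
#'   of the input read.
#' @export
trim_reads <- function(reads, quality_limit = 0.05) {
  check_cols(reads, c("id", "seq", "qual"), "reads")
  check_number(quality_limit, "quality_limit", lower = 0, upper = 1,
               allow_lower = FALSE, allow_upper = FALSE)
  if (nrow(reads) == 0) {
    return(mutate(reads, trim_start = integer(), trim_end = integer()))
  }
  if (anyNA(reads$qual)) stop_mm("trimming requires quality scores for every read")
  if (any(nchar(reads$qual) != nchar(reads$seq))) {
    stop_mm("quality strings must match sequence lengths")
  }
  bounds <- vapply(phred_scores(reads$qual), function(q) {
    mott_bounds(quality_limit - 10^(-q / 10))
  }, integer(2))
  start <- bounds[1, ]
  end <- bounds[2, ]
  empty <- start == 0L
  mutate(reads,
         seq = ifelse(empty, "", substr(.data$seq, start, end)),
         qual = ifelse(empty, "", substr(.data$qual, start, end)),
         trim_start = start, trim_end = end)
}

# maximal-scoring contiguous subsequence; ties leftmost start then longest.
# returns c(start, end) 1-based, or c(0L, 0L) when all scores are negative.
mott_bounds <- function(s) {
  n <- length(s)
  if (n == 0L) return(c(0L, 0L))
  pre <- c(0, cumsum(s))           # pre[j+1] = sum of s[1..j]
  minpre <- cummin(pre[1:n])       # min over prefixes 0..i-1 for end i
  # first index (0-based prefix) achieving the running minimum
  firstmin <- integer(n)
  cur_min <- pre[1]
  cur_idx <- 0L
  for (i in 1:n) {
    if (pre[i] < cur_min) { cur_min <- pre[i]; cur_idx <- i - 1L }
    firstmin[i] <- cur_idx
  }
  val <- pre[2:(n + 1)] - minpre
  best <- max(val)
  if (best <= 0) return(c(0L, 0L))
  ends <- which(val == best)
  starts <- firstmin[ends] + 1L
  pick <- which(starts == min(starts))
  pick <- pick[length(pick)]       # leftmost start, then longest (largest end)
  c(starts[pick], ends[pick])
}

#' Filter reads on length and ambiguity
#'
#' Keeps exactly the reads at least `min_length` bases long (inclusive) with
#' at most `max_ambiguous` ambiguous (N) bases.
#'
#' @param reads Tibble with columns `id` and `seq` (and optionally `qual`).
#' @param min_length Minimum length in bp, inclusive; default 100.
#' @param max_ambiguous Maximum N count; default 2.
#' @return The kept subset of `reads`, order preserved.
#' @export
filter_reads <- function(reads, min_length = 100L, max_ambiguous = 2L) {
  check_cols(reads, c("id", "seq"), "reads")
  check_number(min_length, "min_length", lower = 1)
  check_number(max_ambiguous, "max_ambiguous", lower = 0)
  keep <- nchar(reads$seq) >= min_length &
    stringr::str_count(reads$seq, stringr::fixed("N")) <= max_ambiguous
  reads[keep, , drop = FALSE]
}
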