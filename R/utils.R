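# internal helpers shared across modules

stop_mm <- function(...) abort(paste0(...), class = "markermine_error")

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_mm("`", name, "` must be TRUE or FALSE")
  }
  invisible(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (allow_lower) x >= lower else x > lower) &&
    (if (allow_upper) x <= upper else x < upper)
  if (!ok) {
    stop_mm("`", name, "` must be a single number in ",
            if (allow_lower) "[" else "(", lower, ", ", upper,
            if (allow_upper) "]" else ")")
  }
  invisible(x)
}

check_cols <- function(df, cols, name) {
  if (!is.data.frame(df)) stop_mm("`", name, "` must be a data frame")
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_mm("`", name, "` is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}

# run `expr` under a fixed seed without disturbing the caller's RNG stream;
# a NULL seed uses (and advances) the current stream
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# Phred+33 encoded quality string -> integer scores
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) return(NULL)
    as.integer(charToRaw(q)) - 33L
  })
}

scores_to_qual <- function(scores) {
  vapply(scores, function(s) rawToChar(as.raw(pmin(s, 93L) + 33L)), character(1))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
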