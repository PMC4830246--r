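# independent brute-force oracles used to validate the implementation

blosum62_matrix <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# plain-R affine-gap Smith-Waterman score (gap of length k costs open + k*ext)
sw_oracle_score <- function(a, b, open = 11, ext = 1, mat = blosum62_matrix) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      E[i + 1, j + 1] <- max(E[i + 1, j] - ext, H[i + 1, j] - open - ext)
      F[i + 1, j + 1] <- max(F[i, j + 1] - ext, H[i, j + 1] - open - ext)
      H[i + 1, j + 1] <- max(0, H[i, j] + mat[a[i], b[j]],
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# O(n^2) maximal-scoring-subsequence oracle; ties leftmost start then longest
mott_oracle <- function(s) {
  n <- length(s)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- sum(s[i:j])
      better <- v > best ||
        (v == best && best > 0 && (i < bi || (i == bi && j > bj)))
      if (better) { best <- v; bi <- i; bj <- j }
    }
  }
  if (best <= 0) c(0L, 0L) else c(bi, bj)
}

# brute-force LCA oracle: intersect full ancestor paths, take deepest node
lca_oracle <- function(taxids, taxonomy) {
  parent <- stats::setNames(taxonomy$parent, taxonomy$taxid)
  path_up <- function(t) {
    p <- character()
    while (TRUE) {
      p <- c(p, t)
      if (parent[[t]] == t) break
      t <- parent[[t]]
    }
    p
  }
  paths <- lapply(unique(taxids), path_up)
  common <- Reduce(intersect, paths)
  depth <- vapply(common, function(t) length(path_up(t)), integer(1))
  common[which.max(depth)]
}

random_taxonomy <- function(n_nodes) {
  taxid <- paste0("t", seq_len(n_nodes))
  parent <- c("t1", vapply(2:n_nodes, function(i) {
    taxid[sample.int(i - 1L, 1)]
  }, character(1)))
  taxonomy_table(tibble::tibble(taxid = taxid, parent = parent,
                                rank = "node", name = taxid))
}

# one-line recomputation of BSR decisions from the two raw hit tables
bsr_decision_oracle <- function(custom_hits, background_hits, cutoffs,
                                dataset = NULL) {
  if (!is.null(dataset) && "dataset" %in% names(cutoffs)) {
    cutoffs <- cutoffs[cutoffs$dataset == dataset, ]
  }
  pick_best <- function(h) {
    h <- h[order(h$qseqid, -h$bitscore, h$evalue, h$sseqid), ]
    h[!duplicated(h$qseqid), ]
  }
  bc <- pick_best(as.data.frame(custom_hits))
  bb <- pick_best(as.data.frame(background_hits))
  bg <- stats::setNames(bb$bitscore, bb$qseqid)
  cut <- stats::setNames(cutoffs$cutoff, cutoffs$family)
  out <- data.frame(read_id = bc$qseqid, family = bc$family,
                    stringsAsFactors = FALSE)
  out$ratio <- bc$bitscore / unname(bg[out$read_id])
  out$decision <- ifelse(is.na(out$ratio), "kept",
                         ifelse(out$ratio >= unname(cut[out$family]),
                                "kept", "discarded"))
  out[order(out$read_id), ]
}

random_aa <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, TRUE),
        collapse = "")
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# point-mutate a nucleotide sequence (substitutions only)
mutate_nt <- function(seq, divergence) {
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < divergence
  chars[hit] <- vapply(chars[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(chars, collapse = "")
}
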