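AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(length_aa) {
  paste(sample(AA20, length_aa, replace = TRUE), collapse = "")
}

random_dna <- function(length_nt) {
  paste(sample(c("A", "C", "G", "T"), length_nt, replace = TRUE), collapse = "")
}

#' Mutate a protein sequence by point substitution
#'
#' Each position is substituted with probability `divergence` by a residue
#' drawn uniformly from the other 19 standard amino acids, so the expected
#' identity to the source is `1 - divergence`.
#'
#' @param seq Amino-acid string.
#' @param divergence Substitution probability per site, in `[0, 1]`.
#' @return The mutated sequence.
#' @export
mutate_protein <- function(seq, divergence) {
  check_number(divergence, "divergence", lower = 0, upper = 1)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < divergence
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) sample(setdiff(AA20, a), 1),
                         character(1))
  }
  paste(chars, collapse = "")
}

# codon table for back-translation (stop codons excluded)
codon_choices <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
})

#' Back-translate a protein to a nucleotide coding sequence
#'
#' Codons are drawn uniformly among each residue's synonymous codons, so two
#' independent back-translations of the same protein differ at synonymous
#' sites - the screen under test is a translated search, and embedded genes
#' should not be trivially identical to the reference at the DNA level.
#'
#' @param aa Amino-acid string (standard residues).
#' @return A nucleotide string of length `3 * nchar(aa)`.
#' @export
back_translate <- function(aa) {
  chars <- strsplit(aa, "")[[1]]
  bad <- setdiff(chars, names(codon_choices))
  if (length(bad) > 0) stop_mm("cannot back-translate residue(s): ",
                               paste(unique(bad), collapse = ", "))
  paste(vapply(chars, function(a) {
    ch <- codon_choices[[a]]
    ch[sample.int(length(ch), 1)]
  }, character(1)), collapse = "")
}

#' Generate a synthetic marker-family reference set with decoys
#'
#' Targets are drawn around a family ancestor; decoys are derived from the
#' targets by point substitution at `decoy_divergence`, giving
#' homologous-but-off-target sequences (the narG-like vs nxrA-like
#' situation) that populate the background (NR-proxy) database.
#'
#' @param family Family name used in sequence ids.
#' @param n_targets,n_decoys Numbers of sequences (>= 1).
#' @param target_divergence Per-target divergence from the family ancestor.
#' @param decoy_divergence Divergence of each decoy from its source target;
#'   at 0 the decoys are identical to the targets.
#' @param length_aa Sequence length in residues.
#' @param seed Optional seed; the same seed reproduces the set exactly.
#' @param ancestor Optional ancestor sequence (otherwise random).
#' @return A list with tibbles `targets` and `decoys` (columns `id`, `seq`,
#'   `family`; decoy family is `<family>_decoy`) and the `ancestor` string.
#' @export
make_reference_set <- function(family, n_targets = 4L, n_decoys = 4L,
                               target_divergence = 0.15, decoy_divergence = 0.4,
                               length_aa = 300L, seed = NULL, ancestor = NULL) {
  check_number(n_targets, "n_targets", lower = 1)
  check_number(n_decoys, "n_decoys", lower = 1)
  check_number(target_divergence, "target_divergence", lower = 0, upper = 1)
  check_number(decoy_divergence, "decoy_divergence", lower = 0, upper = 1)
  with_seed_or_not(seed, {
    anc <- ancestor %||% random_protein(length_aa)
    targets <- vapply(seq_len(n_targets), function(i) {
      mutate_protein(anc, target_divergence)
    }, character(1))
    decoys <- vapply(seq_len(n_decoys), function(i) {
      src <- targets[(i - 1L) %% n_targets + 1L]
      mutate_protein(src, decoy_divergence)
    }, character(1))
    list(
      targets = tibble(id = sprintf("%s_t%d", family, seq_len(n_targets)),
                       seq = targets, family = family),
      decoys = tibble(id = sprintf("%s_decoy%d", family, seq_len(n_decoys)),
                      seq = decoys, family = paste0(family, "_decoy")),
      ancestor = anc
    )
  })
}

#' Define a community member
#'
#' @param label Taxon label.
#' @param abundance Relative abundance of the member (cellular fraction).
#' @param genome_size Genome length in bp; must accommodate the payload.
#' @param payload Tibble with columns `family`, `copies`, `template_id`,
#'   `template_aa`: the marker genes this genome carries. May be empty.
#' @param lineage Optional lineage string.
#' @return A `community_member` list.
#' @export
community_member <- function(label, abundance, genome_size = 30000L,
                             payload = NULL, lineage = NA_character_) {
  check_number(abundance, "abundance", lower = 0, upper = 1)
  check_number(genome_size, "genome_size", lower = 1)
  payload <- payload %||% tibble(family = character(), copies = integer(),
                                 template_id = character(), template_aa = character())
  check_cols(payload, c("family", "copies", "template_id", "template_aa"), "payload")
  if (any(payload$copies < 0) || any(payload$copies != as.integer(payload$copies))) {
    stop_mm("copy numbers must be non-negative integers")
  }
  gene_bp <- sum(3 * nchar(payload$template_aa) * payload$copies)
  if (genome_size < gene_bp) {
    stop_mm("genome_size (", genome_size, ") smaller than payload (", gene_bp, " bp)")
  }
  structure(list(label = label, abundance = abundance,
                 genome_size = as.integer(genome_size),
                 payload = payload, lineage = lineage),
            class = "community_member")
}

#' Assemble a community profile
#'
#' @param members List of [community_member()] objects.
#' @param background_fraction Fraction of reads drawn from a neutral
#'   (marker-free, rpoB-free) background genome; member abundances plus this
#'   fraction must sum to 1 within 1e-9.
#' @param background_genome_size Length of the neutral background genome.
#' @return A `community_profile` object.
#' @export
community_profile <- function(members, background_fraction = 0,
                              background_genome_size = 30000L) {
  if (length(members) == 0) stop_mm("a community needs at least one member")
  if (!all(vapply(members, inherits, logical(1), "community_member"))) {
    stop_mm("`members` must be a list of community_member objects")
  }
  check_number(background_fraction, "background_fraction", lower = 0, upper = 1)
  total <- sum(vapply(members, `[[`, numeric(1), "abundance")) + background_fraction
  if (abs(total - 1) > 1e-9) {
    stop_mm("abundances plus background_fraction must sum to 1 (got ", total, ")")
  }
  labels <- vapply(members, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop_mm("duplicated member label(s)")
  structure(list(members = members, background_fraction = background_fraction,
                 background_genome_size = as.integer(background_genome_size)),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat("<community_profile> ", length(x$members), " members, background ",
      format(x$background_fraction), "\n", sep = "")
  for (m in x$members) {
    cat(sprintf("  %-18s ab %.3f  genome %d bp  genes: %s\n", m$label,
                m$abundance, m$genome_size,
                if (nrow(m$payload) == 0) "-" else
                  paste(m$payload$family, collapse = ", ")))
  }
  invisible(x)
}

# materialise genomes: implant back-translated payload genes at random,
# non-overlapping positions separated by random neutral sequence
build_genomes <- function(profile) {
  genomes <- list()
  genes <- list()
  for (m in profile$members) {
    pl <- m$payload[rep(seq_len(nrow(m$payload)), m$payload$copies), , drop = FALSE]
    if (nrow(pl) > 0) {
      gene_nt <- vapply(pl$template_aa, back_translate, character(1))
      glen <- nchar(gene_nt)
      spare <- m$genome_size - sum(glen)
      cuts <- sort(runif(nrow(pl)))
      gaps <- floor(spare * diff(c(0, cuts)))
      last_gap <- spare - sum(gaps)
      parts <- character(2 * nrow(pl) + 1)
      starts <- integer(nrow(pl))
      pos <- 0L
      for (i in seq_len(nrow(pl))) {
        parts[2 * i - 1] <- random_dna(gaps[i])
        pos <- pos + gaps[i]
        starts[i] <- pos + 1L
        parts[2 * i] <- gene_nt[i]
        pos <- pos + glen[i]
      }
      parts[2 * nrow(pl) + 1] <- random_dna(last_gap)
      genomes[[m$label]] <- paste(parts, collapse = "")
      genes[[m$label]] <- tibble(taxon = m$label, family = pl$family,
                                 template_id = pl$template_id,
                                 start = starts, end = starts + glen - 1L)
    } else {
      genomes[[m$label]] <- random_dna(m$genome_size)
    }
  }
  if (profile$background_fraction > 0) {
    genomes[["background"]] <- random_dna(profile$background_genome_size)
  }
  list(genomes = genomes, genes = bind_rows(genes))
}

apply_read_errors <- function(seq, error_rate, indel_rate) {
  v <- utf8ToInt(seq)
  n <- length(v)
  nt <- utf8ToInt("ACGT")
  nsub <- rbinom(1, n, error_rate)
  if (nsub > 0) {
    pos <- sample.int(n, nsub)
    for (p in pos) {
      v[p] <- sample(setdiff(nt, v[p]), 1)
    }
  }
  nind <- rbinom(1, n, indel_rate)
  if (nind > 0) {
    for (k in seq_len(nind)) {
      p <- sample.int(length(v), 1)
      if (runif(1) < 0.5) {
        v <- append(v, sample(nt, 1), after = p)     # insertion
      } else if (length(v) > 1) {
        v <- v[-p]                                   # deletion
      }
    }
  }
  intToUtf8(v)
}

#' Simulate metagenomic reads with per-read ground truth
#'
#' Reads are drawn from the community's genomes proportionally to abundance
#' times genome size, at uniform positions and random strand, with lengths
#' from a clamped normal model. Errors are i.i.d. substitutions at
#' `error_rate` plus rare 1-bp indels at `indel_rate`; base qualities encode
#' the substitution rate (with small jitter). A read's truth origin is the
#' marker family whose gene covers at least 50% of the read, mirroring the
#' 50%-of-read mapping thresholds used by the screening pipeline itself;
#' all other reads are labelled `"background"`.
#'
#' @param profile A [community_profile()].
#' @param n_reads Number of reads (>= 1).
#' @param read_length_mean,read_length_sd Read-length model (defaults 230
#'   and 30 bp, clamped to `[100, 300]`).
#' @param error_rate Substitution probability per base, in `[0, 0.25)`.
#' @param indel_rate 1-bp indel probability per base (default
#'   `error_rate / 20`).
#' @param seed Optional seed; the same seed reproduces reads byte-for-byte.
#' @param id_prefix Prefix for read ids.
#' @return A list with `reads` (tibble `id`, `seq`, `qual`), `truth` (tibble
#'   `read_id`, `taxon`, `origin`, `start`, `end` - coordinates of the
#'   sampled fragment on its source genome), `genomes` (named character) and
#'   `genes` (gene coordinate tibble).
#' @export
simulate_reads <- function(profile, n_reads, read_length_mean = 230,
                           read_length_sd = 30, error_rate = 0.01,
                           indel_rate = error_rate / 20, seed = NULL,
                           id_prefix = "read") {
  if (!inherits(profile, "community_profile")) {
    stop_mm("`profile` must be a community_profile")
  }
  check_number(n_reads, "n_reads", lower = 1)
  check_number(error_rate, "error_rate", lower = 0, upper = 0.25,
               allow_upper = FALSE)
  check_number(indel_rate, "indel_rate", lower = 0, upper = 0.25,
               allow_upper = FALSE)
  with_seed_or_not(seed, {
    built <- build_genomes(profile)
    genomes <- built$genomes
    glen <- vapply(genomes, nchar, integer(1))
    ab <- c(vapply(profile$members, `[[`, numeric(1), "abundance"),
            if (profile$background_fraction > 0) profile$background_fraction)
    labels <- names(genomes)
    w <- ab * glen[labels]
    midx <- sample.int(length(labels), n_reads, replace = TRUE, prob = w)
    lens <- pmin(pmax(round(rnorm(n_reads, read_length_mean, read_length_sd)),
                      100L), 300L)
    lens <- pmin(lens, glen[labels][midx])
    starts <- floor(runif(n_reads) * (glen[labels][midx] - lens + 1)) + 1L
    ends <- starts + lens - 1L
    seqs <- substring(unlist(genomes[labels])[midx], starts, ends)
    flip <- runif(n_reads) < 0.5
    if (any(flip)) seqs[flip] <- revcomp_chr(seqs[flip])
    if (error_rate > 0 || indel_rate > 0) {
      seqs <- vapply(seqs, apply_read_errors, character(1),
                     error_rate = error_rate, indel_rate = indel_rate,
                     USE.NAMES = FALSE)
    }
    qbase <- if (error_rate <= 0) 40L else
      min(40L, max(2L, as.integer(round(-10 * log10(error_rate)))))
    quals <- vapply(nchar(seqs), function(n) {
      scores_to_qual(list(pmin(40L, pmax(2L, qbase + sample(-2:2, n, TRUE)))))
    }, character(1))

    # truth: >= 50% of the sampled fragment inside a marker gene
    origin <- rep("background", n_reads)
    gtab <- built$genes
    if (!is.null(gtab) && nrow(gtab) > 0) {
      for (lab in unique(gtab$taxon)) {
        ridx <- which(labels[midx] == lab)
        if (length(ridx) == 0) next
        sub <- gtab[gtab$taxon == lab, ]
        for (g in seq_len(nrow(sub))) {
          ov <- pmin(ends[ridx], sub$end[g]) - pmax(starts[ridx], sub$start[g]) + 1L
          hit <- ov >= 0.5 * lens[ridx]
          origin[ridx[hit]] <- sub$family[g]
        }
      }
    }
    ids <- sprintf("%s%06d", id_prefix, seq_len(n_reads))
    list(
      reads = tibble(id = ids, seq = unname(seqs), qual = unname(quals)),
      truth = tibble(read_id = ids, taxon = labels[midx], origin = origin,
                     start = starts, end = ends),
      genomes = genomes,
      genes = built$genes
    )
  })
}

#' Score kept-read decisions against simulation truth
#'
#' @param decisions Tibble of kept reads with columns `read_id`, `family`
#'   (the assigned screening family). If a `decision` column is present only
#'   rows with `decision == "kept"` are scored.
#' @param truth Truth tibble from [simulate_reads()] (`read_id`, `origin`).
#' @param origin_map Optional tibble `origin`, `family` translating
#'   fine-grained truth origins to screening families; unmapped origins
#'   count as `"background"`.
#' @return A tibble per family: `n_truth`, `n_kept`, `tp`, `fp`, `fn`,
#'   `precision` (`NA` when nothing was kept) and `recall` (`NA` for
#'   families with no truth reads).
#' @export
evaluate_against_truth <- function(decisions, truth, origin_map = NULL) {
  check_cols(decisions, c("read_id", "family"), "decisions")
  check_cols(truth, c("read_id", "origin"), "truth")
  if ("decision" %in% names(decisions)) {
    decisions <- filter(decisions, .data$decision == "kept")
  }
  unknown <- setdiff(decisions$read_id, truth$read_id)
  if (length(unknown) > 0) {
    stop_mm("decision(s) for unknown read id(s): ",
            paste(head(unknown, 5), collapse = ", "))
  }
  tr <- select(truth, "read_id", "origin")
  if (!is.null(origin_map)) {
    check_cols(origin_map, c("origin", "family"), "origin_map")
    tr <- left_join(tr, origin_map, by = "origin")
    tr$origin <- ifelse(is.na(tr$family), "background", tr$family)
    tr$family <- NULL
  }
  joined <- left_join(tr, select(decisions, "read_id", kept_as = "family"),
                      by = "read_id")
  fams <- sort(setdiff(union(joined$origin, joined$kept_as), c("background", NA)))
  purrr::map_dfr(fams, function(f) {
    tp <- sum(joined$origin == f & !is.na(joined$kept_as) & joined$kept_as == f)
    fp <- sum(joined$origin != f & !is.na(joined$kept_as) & joined$kept_as == f)
    fn <- sum(joined$origin == f & (is.na(joined$kept_as) | joined$kept_as != f))
    n_truth <- tp + fn
    tibble(family = f, n_truth = n_truth, n_kept = tp + fp,
           tp = tp, fp = fp, fn = fn,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           recall = if (n_truth > 0) tp / n_truth else NA_real_)
  })
}
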