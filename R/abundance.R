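#' Length- and library-size-normalized read count
#'
#' Normalized read count = raw count x 1,000 bp x 1,000,000 reads /
#' (gene length in bp x total reads in the metagenome) - i.e. reads per
#' kilobase of gene per million metagenome reads. The value is linear in the
#' raw count and inversely linear in gene length and library size, so
#' normalized counts are comparable across genes of different lengths and
#' libraries of different depths.
#'
#' @param raw_count Number of reads assigned to the gene (>= 0).
#' @param gene_length_bp Gene length in bp (> 0).
#' @param total_reads Total reads in the metagenome (> 0).
#' @return The normalized count (vectorised).
#' @examples
#' normalize_count(3, 900, 1641277) # ~2.031
#' @export
normalize_count <- function(raw_count, gene_length_bp, total_reads) {
  if (any(raw_count < 0)) stop_mm("raw_count must be >= 0")
  if (any(gene_length_bp <= 0)) stop_mm("gene_length_bp must be positive")
  if (any(total_reads <= 0)) stop_mm("total_reads must be positive")
  raw_count * 1000 * 1e6 / (gene_length_bp * total_reads)
}

#' Express a normalized count as a fraction of normalized rpoB
#'
#' rpoB is a universal single-copy gene, so its normalized count estimates
#' the per-genome sequencing depth of the whole cellular community; the
#' ratio estimates the fraction of genomes carrying the marker. Values above
#' 1 are possible for multi-copy markers (no copy-number correction is
#' applied).
#'
#' @param family_normalized Normalized count(s) of the marker family.
#' @param rpob_normalized Normalized count of rpoB (> 0).
#' @return The fraction(s).
#' @export
fraction_of_rpob <- function(family_normalized, rpob_normalized) {
  if (any(rpob_normalized <= 0)) {
    stop_mm("rpoB normalized count must be positive; without detected rpoB ",
            "reads the community depth reference is undefined")
  }
  family_normalized / rpob_normalized
}

#' Median reference gene length per family
#'
#' The per-family gene length used for normalization, taken as the median
#' ungapped reference length in bp (amino-acid length x 3). Provide an
#' override column to [abundance_table()] when true lengths are known.
#'
#' @param reference Tibble `id`, `seq` (amino acid), `family`.
#' @return Tibble `family`, `gene_length_bp`.
#' @export
reference_gene_lengths <- function(reference) {
  check_cols(reference, c("seq", "family"), "reference")
  reference |>
    group_by(.data$family) |>
    summarise(gene_length_bp = stats::median(nchar(.data$seq)) * 3, .groups = "drop")
}

#' Build a per-family abundance table
#'
#' Combines raw kept-read counts with gene lengths and library sizes into
#' normalized counts and fractions of normalized rpoB.
#'
#' @param counts Tibble `family`, `raw_count`, optionally `dataset`.
#' @param gene_lengths Tibble `family`, `gene_length_bp` (e.g. from
#'   [reference_gene_lengths()]).
#' @param total_reads Named numeric vector of library sizes per dataset, or a
#'   single number when `counts` has no `dataset` column.
#' @param rpob_family Name of the single-copy reference family (default
#'   `"rpoB"`); must be present in `counts` with a positive count for the
#'   rpoB fraction to be defined.
#' @return A tibble `family`, `dataset`, `raw_count`, `gene_length_bp`,
#'   `total_reads`, `normalized`, `rpob_fraction`.
#' @export
abundance_table <- function(counts, gene_lengths, total_reads,
                            rpob_family = "rpoB") {
  check_cols(counts, c("family", "raw_count"), "counts")
  check_cols(gene_lengths, c("family", "gene_length_bp"), "gene_lengths")
  if (!"dataset" %in% names(counts)) counts$dataset <- "all"
  if (is.null(names(total_reads))) {
    if (length(total_reads) != 1L) {
      stop_mm("`total_reads` must be named per dataset or a single number")
    }
    total_reads <- setNames(rep(total_reads, length(unique(counts$dataset))),
                            unique(counts$dataset))
  }
  missing <- setdiff(unique(counts$dataset), names(total_reads))
  if (length(missing) > 0) {
    stop_mm("missing total_reads for dataset(s): ", paste(missing, collapse = ", "))
  }
  missing <- setdiff(unique(counts$family), gene_lengths$family)
  if (length(missing) > 0) {
    stop_mm("missing gene length for family(ies): ", paste(missing, collapse = ", "))
  }
  out <- counts |>
    left_join(distinct(gene_lengths, .data$family, .keep_all = TRUE), by = "family") |>
    mutate(total_reads = unname(total_reads[.data$dataset]),
           normalized = normalize_count(.data$raw_count, .data$gene_length_bp,
                                        .data$total_reads))
  rpob <- out |>
    filter(.data$family == rpob_family) |>
    select("dataset", rpob_normalized = "normalized")
  out <- left_join(out, rpob, by = "dataset")
  mutate(out,
         rpob_fraction = ifelse(!is.na(.data$rpob_normalized) & .data$rpob_normalized > 0,
                                .data$normalized / .data$rpob_normalized, NA_real_),
         rpob_normalized = NULL) |>
    select("family", "dataset", "raw_count", "gene_length_bp", "total_reads",
           "normalized", "rpob_fraction")
}

#' Detection-limit abundance estimate for a marker gene
#'
#' Given how many reads a single-copy marker gene should attract if every
#' genome carried it - `expected = (gene_length / genome_size) x total_reads`
#' - the observed count yields a fold-depletion factor and an abundance
#' estimate for the carrying population:
#' `fold_lower = expected / observed` and
#' `abundance_percent = 100 x observed / expected`.
#' With the defaults (900 bp gene, 3 Mbp average genome) and a 1.6-million
#' read library, 3 observed nifH reads give 480 expected reads (3 per 10,000
#' sequenced), a 160-fold depletion, and a 0.6% diazotroph abundance
#' estimate (0.625% before one-decimal rounding).
#'
#' @param observed_reads Observed read count (>= 0).
#' @param gene_length_bp Marker gene length in bp (default 900, the nifH
#'   length used in the worked example).
#' @param genome_size_bp Assumed average genome size (default 3 Mbp).
#' @param total_reads Total reads in the metagenome.
#' @return A tibble `observed_reads`, `expected_reads`, `fold_lower`
#'   (`Inf` when nothing was observed), `abundance_percent`.
#' @examples
#' estimate_detection_abundance(3, 900, 3e6, 1.6e6)
#' @export
estimate_detection_abundance <- function(observed_reads, gene_length_bp = 900,
                                         genome_size_bp = 3e6, total_reads) {
  if (any(observed_reads < 0)) stop_mm("observed_reads must be >= 0")
  if (any(gene_length_bp <= 0) || any(genome_size_bp <= 0) || any(total_reads <= 0)) {
    stop_mm("gene_length_bp, genome_size_bp and total_reads must be positive")
  }
  expected <- gene_length_bp / genome_size_bp * total_reads
  if (any(expected == 0)) stop_mm("expected read count is zero")
  tibble(observed_reads = observed_reads,
         expected_reads = expected,
         fold_lower = ifelse(observed_reads == 0, Inf, expected / observed_reads),
         abundance_percent = 100 * observed_reads / expected)
}
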