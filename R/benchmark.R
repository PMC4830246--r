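#' Synthetic benchmark reference sets
#'
#' Builds the reference databases for the default two-station benchmark:
#' seven screening families (the homolog pairs hao/hdh and
#' narG/nxrA - screened combined - plus nirK, nirS, nosZ, hzsA and the
#' single-copy reference rpoB). Homolog pairs share a common ancestor so
#' that hao and hdh (and narG and the two nxrA subset lineages) are
#' genuinely homologous-but-distinct, as in the real gene families. Decoys
#' at `decoy_divergence` from the targets populate the background (NR-proxy)
#' database.
#'
#' @param seed Seed making the whole reference construction reproducible.
#' @param length_aa Marker protein length in residues (default 300, i.e. a
#'   900-bp gene, the nifH-sized marker used in the detection-limit
#'   arithmetic; rpoB uses 400 residues).
#' @param decoy_divergence Divergence of decoys from targets (default 0.4).
#' @return A list with `custom` (target tibble with screening `family`),
#'   `background` (decoy tibble), `subsets` (`nxrA_A`, `nxrA_B` amino-acid
#'   tibbles), `hdh_nt` (nucleotide hdh reference copies), `fine` (named
#'   list of per-lineage target tibbles used to derive community templates)
#'   and `origin_map` (fine origin to screening family).
#' @export
benchmark_reference_sets <- function(seed = 20160421L, length_aa = 300L,
                                     decoy_divergence = 0.4) {
  with_seed_or_not(seed, {
    fine <- list()
    decoys <- list()

    simple <- function(family, n_targets = 4L, len = length_aa) {
      rs <- make_reference_set(family, n_targets = n_targets, n_decoys = 4L,
                               target_divergence = 0.15,
                               decoy_divergence = decoy_divergence,
                               length_aa = len)
      fine[[family]] <<- rs$targets
      decoys[[family]] <<- rs$decoys
    }
    simple("nirK"); simple("nirS"); simple("nosZ"); simple("hzsA")
    simple("rpoB", len = 400L)

    # hao/hdh: two sub-lineages of one octaheme ancestor (~55% cross identity)
    anc <- random_protein(length_aa)
    hao_anc <- mutate_protein(anc, 0.25)
    hdh_anc <- mutate_protein(anc, 0.25)
    hao <- make_reference_set("hao", n_targets = 3L, n_decoys = 3L,
                              target_divergence = 0.08,
                              decoy_divergence = decoy_divergence,
                              ancestor = hao_anc, length_aa = length_aa)
    hdh <- make_reference_set("hdh", n_targets = 2L, n_decoys = 2L,
                              target_divergence = 0.08,
                              decoy_divergence = decoy_divergence,
                              ancestor = hdh_anc, length_aa = length_aa)
    fine$hao <- hao$targets
    fine$hdh <- hdh$targets
    decoys$hao_hdh <- bind_rows(hao$decoys, hdh$decoys)

    # narG/nxrA: molybdopterin oxidoreductase ancestor with a narG lineage
    # and a polyphyletic nxrA lineage split into two subsets
    anc <- random_protein(length_aa)
    narg_anc <- mutate_protein(anc, 0.18)
    nxra_anc <- mutate_protein(anc, 0.18)
    narg <- make_reference_set("narG", n_targets = 4L, n_decoys = 4L,
                               target_divergence = 0.08,
                               decoy_divergence = decoy_divergence,
                               ancestor = narg_anc, length_aa = length_aa)
    nxra_a <- make_reference_set("nxrA_A", n_targets = 3L, n_decoys = 2L,
                                 target_divergence = 0.06,
                                 decoy_divergence = decoy_divergence,
                                 ancestor = mutate_protein(nxra_anc, 0.12),
                                 length_aa = length_aa)
    nxra_b <- make_reference_set("nxrA_B", n_targets = 3L, n_decoys = 2L,
                                 target_divergence = 0.06,
                                 decoy_divergence = decoy_divergence,
                                 ancestor = mutate_protein(nxra_anc, 0.12),
                                 length_aa = length_aa)
    fine$narG <- narg$targets
    fine$nxrA_A <- nxra_a$targets
    fine$nxrA_B <- nxra_b$targets
    decoys$narG_nxrA <- narg$decoys

    screen_of <- c(hao = "hao_hdh", hdh = "hao_hdh", narG = "narG_nxrA",
                   nxrA_A = "narG_nxrA", nxrA_B = "narG_nxrA",
                   nirK = "nirK", nirS = "nirS", nosZ = "nosZ",
                   hzsA = "hzsA", rpoB = "rpoB")
    custom <- bind_rows(lapply(names(fine), function(f) {
      mutate(fine[[f]], family = unname(screen_of[f]))
    }))
    background <- bind_rows(decoys)
    hdh_nt <- tibble(id = paste0(hdh$targets$id, "_nt"),
                     seq = vapply(hdh$targets$seq, back_translate, character(1)))
    list(custom = custom, background = background,
         subsets = list(nxrA_A = nxra_a$targets, nxrA_B = nxra_b$targets),
         hdh_nt = hdh_nt, fine = fine,
         origin_map = tibble(origin = names(screen_of),
                             family = unname(screen_of)))
  })
}

# station compositions for the two-community benchmark; abundances are
# fixed design constants of the mock communities
benchmark_members <- function(station) {
  switch(station,
    PA2 = list(
      list("nitrospina_like", 0.07, list(nxrA_B = 1)),
      list("nob_novel",       0.05, list(nxrA_A = 1)),
      list("aob_like",        0.09, list(hao = 1)),
      list("denitrifier_1",   0.12, list(narG = 1, nirK = 1, nosZ = 1)),
      list("denitrifier_2",   0.08, list(narG = 1, nirS = 1, nosZ = 1)),
      list("nirk_organism",   0.06, list(nirK = 1)),
      list("anammox_like",    0.03, list(hdh = 1, hzsA = 1, nxrA_B = 1)),
      list("heterotroph_1",   0.12, list()),
      list("decoy_narg",      0.04, list(narG_decoy = 1)),
      list("decoy_nirk",      0.04, list(nirK_decoy = 1)),
      list("decoy_haohdh",    0.03, list(hao_decoy = 1)),
      list("decoy_nosz",      0.03, list(nosZ_decoy = 1))
    ),
    PA5 = list(
      list("anammox_like",    0.15, list(hdh = 1, hzsA = 1, nxrA_B = 1)),
      list("scalindua_2",     0.07, list(hdh = 1, hzsA = 1)),
      list("nitrospina_like", 0.05, list(nxrA_B = 1)),
      list("denitrifier_1",   0.10, list(narG = 1, nirK = 1, nosZ = 1)),
      list("denitrifier_3",   0.09, list(narG = 1, nirS = 1, nosZ = 1)),
      list("nirs_organism",   0.05, list(nirS = 1)),
      list("aob_like",        0.04, list(hao = 1)),
      list("heterotroph_2",   0.12, list()),
      list("decoy_narg",      0.04, list(narG_decoy = 1)),
      list("decoy_nirs",      0.03, list(nirS_decoy = 1)),
      list("decoy_hzsa",      0.03, list(hzsA_decoy = 1)),
      list("decoy_haohdh",    0.03, list(hao_decoy = 1))
    ),
    stop_mm("unknown station: ", station)
  )
}

#' Default benchmark community for one station
#'
#' Builds the mock community emulating two oxygen-minimum-zone stations: a suboxic,
#' nitrifier-leaning community (`PA2`) and an anoxic-core, anammox-heavy
#' community (`PA5`). Marker-carrying members get gene templates derived
#' from a reference target at `member_divergence` (novel-but-related
#' lineages); decoy members carry a decoy gene verbatim (database-known
#' off-target organisms, whose reads hit the background database near
#' perfectly). Every cellular member carries a single-copy rpoB. The
#' remaining fraction is neutral background.
#'
#' @param station `"PA2"` or `"PA5"`.
#' @param refsets Reference sets from [benchmark_reference_sets()].
#' @param member_divergence Divergence of member gene templates from their
#'   reference target (default 0.05).
#' @param genome_size Genome size per member in bp (default 30,000 - a
#'   desk-scale stand-in; fractions of rpoB are genome-size-invariant).
#' @param seed Seed for template derivation.
#' @return A [community_profile()].
#' @export
benchmark_profile <- function(station = c("PA2", "PA5"), refsets,
                              member_divergence = 0.05,
                              genome_size = 30000L, seed = 1L) {
  station <- match.arg(station)
  spec <- benchmark_members(station)
  fine <- refsets$fine
  decoy_pool <- refsets$background
  with_seed_or_not(seed, {
    members <- lapply(spec, function(m) {
      fams <- names(m[[3]])
      rows <- lapply(seq_along(fams), function(i) {
        f <- fams[i]
        copies <- m[[3]][[i]]
        if (grepl("_decoy$", f)) {
          base <- sub("_decoy$", "", f)
          pool <- decoy_pool[startsWith(decoy_pool$id, paste0(base, "_decoy")), ]
          j <- sample.int(nrow(pool), 1)
          tibble(family = f, copies = as.integer(copies),
                 template_id = pool$id[j], template_aa = pool$seq[j])
        } else {
          pool <- fine[[f]]
          j <- sample.int(nrow(pool), 1)
          tibble(family = f, copies = as.integer(copies),
                 template_id = pool$id[j],
                 template_aa = mutate_protein(pool$seq[j], member_divergence))
        }
      })
      # every cellular organism carries one rpoB
      j <- sample.int(nrow(fine$rpoB), 1)
      rows <- c(rows, list(tibble(family = "rpoB", copies = 1L,
                                  template_id = fine$rpoB$id[j],
                                  template_aa = mutate_protein(fine$rpoB$seq[j],
                                                               member_divergence))))
      community_member(m[[1]], m[[2]], genome_size, bind_rows(rows))
    })
    background_fraction <- 1 - sum(vapply(spec, `[[`, numeric(1), 2))
    community_profile(members, background_fraction, genome_size)
  })
}

#' Numeric benchmark cutoffs per screening family
#'
#' The per-family BSR cutoffs used on the synthetic benchmark, taken from
#' the packaged per-gene defaults ([table1_cutoffs()]) where a numeric cutoff exists (narG/nxrA 0.5,
#' nirK 0.55, nirS 0.6, nosZ 0.75-0.8, hzsA 0.75, hao/hdh 0.75). rpoB, a
#' manually screened family in [table1_cutoffs()], gets 0.6 here so the
#' benchmark runs unattended.
#'
#' @return Tibble `family`, `dataset`, `cutoff`, `manual`.
#' @export
benchmark_cutoffs <- function() {
  long <- function(family, pa2, pa5) {
    tibble(family = family, dataset = c("PA2", "PA5"), cutoff = c(pa2, pa5))
  }
  out <- bind_rows(
    long("hao_hdh", 0.75, 0.75),
    long("narG_nxrA", 0.5, 0.5),
    long("nirK", 0.55, 0.55),
    long("nirS", 0.6, 0.6),
    long("nosZ", 0.8, 0.75),
    long("hzsA", 0.75, 0.75),
    long("rpoB", 0.6, 0.6)
  )
  mutate(out, manual = FALSE)
}

#' Synthetic taxonomy for the benchmark reference sets
#'
#' A small rooted taxonomy placing each reference target in its own genus
#' under a per-lineage clade, for exercising the LCA classifier on pipeline
#' output.
#'
#' @param refsets Reference sets from [benchmark_reference_sets()].
#' @return A list with `taxonomy` (a [taxonomy_table()]) and `subject_taxa`
#'   (tibble `sseqid`, `taxid`).
#' @export
benchmark_taxonomy <- function(refsets) {
  rows <- list(tibble(taxid = "root", parent = "root", rank = "root",
                      name = "root"))
  map <- list()
  for (f in names(refsets$fine)) {
    clade <- paste0("clade_", f)
    rows <- c(rows, list(tibble(taxid = clade, parent = "root",
                                rank = "clade", name = clade)))
    tg <- refsets$fine[[f]]
    rows <- c(rows, list(tibble(taxid = paste0("g_", tg$id), parent = clade,
                                rank = "genus", name = paste0("g_", tg$id))))
    map <- c(map, list(tibble(sseqid = tg$id, taxid = paste0("g_", tg$id))))
  }
  list(taxonomy = taxonomy_table(bind_rows(rows)),
       subject_taxa = bind_rows(map))
}
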