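test_that("reference sets are deterministic and respect divergence settings", {
  a <- make_reference_set("nirK", seed = 99)
  b <- make_reference_set("nirK", seed = 99)
  expect_identical(a, b)
  # zero-divergence decoys are identical to their source targets
  z <- make_reference_set("fam", n_targets = 2, n_decoys = 2,
                          decoy_divergence = 0, seed = 5)
  expect_equal(z$decoys$seq, z$targets$seq)
  expect_error(make_reference_set("fam", decoy_divergence = 1.4), "divergence")
})

test_that("decoys at divergence 0.4 sit near 60% identity to their source target", {
  rs <- make_reference_set("fam", n_targets = 4, n_decoys = 8,
                           decoy_divergence = 0.4, length_aa = 300, seed = 6)
  ident <- vapply(seq_len(8), function(i) {
    src <- strsplit(rs$targets$seq[(i - 1) %% 4 + 1], "")[[1]]
    dec <- strsplit(rs$decoys$seq[i], "")[[1]]
    mean(src == dec)
  }, numeric(1))
  expect_gte(mean(ident) * 100, 55)
  expect_lte(mean(ident) * 100, 65)
})

test_that("community profiles validate abundances, payload fit and copy numbers", {
  pl <- tibble::tibble(family = "f", copies = 1L, template_id = "t",
                       template_aa = random_aa(100))
  m <- community_member("org", 0.4, genome_size = 1000, payload = pl)
  expect_s3_class(community_profile(list(m), background_fraction = 0.6),
                  "community_profile")
  expect_error(community_profile(list(m), background_fraction = 0.3), "sum to 1")
  expect_error(community_member("org", 0.4, genome_size = 200, payload = pl),
               "smaller than payload")
  expect_error(community_member("org", 0.4, genome_size = 1000,
                                payload = dplyr::mutate(pl, copies = -1L)),
               "copy numbers")
})

test_that("simulation conserves reads, truth rows and is byte-deterministic", {
  pl <- tibble::tibble(family = "f", copies = 1L, template_id = "t",
                       template_aa = random_aa(100))
  prof <- community_profile(list(community_member("org", 0.7, 2000, pl)),
                            background_fraction = 0.3,
                            background_genome_size = 2000)
  s1 <- simulate_reads(prof, 500, seed = 8)
  s2 <- simulate_reads(prof, 500, seed = 8)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$reads), 500L)
  expect_equal(nrow(s1$truth), 500L)
  expect_equal(s1$reads$id, s1$truth$read_id)
  expect_false(anyDuplicated(s1$reads$id) > 0)
  expect_equal(nchar(s1$reads$qual), nchar(s1$reads$seq))
})

test_that("with one gene covering the whole genome every read is that family", {
  aa <- random_aa(120)
  pl <- tibble::tibble(family = "f", copies = 1L, template_id = "t",
                       template_aa = aa)
  prof <- community_profile(list(community_member("org", 1, 360, pl)))
  sim <- simulate_reads(prof, 200, read_length_mean = 150, read_length_sd = 10,
                        error_rate = 0, seed = 9)
  expect_true(all(sim$truth$origin == "f"))
  # error-free simulation gives maximal base qualities
  expect_true(all(strsplit(sim$reads$qual[1], "")[[1]] %in%
                    strsplit(rawToChar(as.raw(33 + 38:40)), "")[[1]]))
})

test_that("family read counts track genomic fractions within binomial error", {
  aa <- random_aa(300) # 900 bp gene
  pl <- tibble::tibble(family = "f", copies = 1L, template_id = "t",
                       template_aa = aa)
  prof <- community_profile(list(
    community_member("carrier", 0.5, 9000, pl),
    community_member("plain", 0.5, 9000)
  ))
  n <- 10000
  sim <- simulate_reads(prof, n, read_length_mean = 150, read_length_sd = 10,
                        error_rate = 0.01, seed = 10)
  # a read is labelled f when >= 50% overlaps the gene; for uniform read
  # starts this window has the gene's own width, so
  # p = 0.5 * gene / genome
  p <- 0.5 * 900 / 9000
  got <- sum(sim$truth$origin == "f")
  expect_lt(abs(got - n * p), 3 * sqrt(n * p * (1 - p)))
  # composition across members matches abundance x genome size weights
  frac_carrier <- mean(sim$truth$taxon == "carrier")
  expect_lt(abs(frac_carrier - 0.5), 3 * sqrt(0.25 / n))
})

test_that("evaluation against truth counts TP/FP/FN per family", {
  truth <- tibble::tibble(read_id = sprintf("r%02d", 1:20),
                          origin = rep(c("f1", "f2", "background", "f1_decoy"),
                                       each = 5))
  # perfect decisions
  dec <- tibble::tibble(read_id = sprintf("r%02d", 1:10),
                        family = rep(c("f1", "f2"), each = 5))
  omap <- tibble::tibble(origin = c("f1", "f2"), family = c("f1", "f2"))
  ev <- evaluate_against_truth(dec, truth, origin_map = omap)
  expect_equal(ev$family, c("f1", "f2"))
  expect_equal(ev$precision, c(1, 1))
  expect_equal(ev$recall, c(1, 1))
  # without a map, unreached origins surface with NA precision, zero recall
  ev_raw <- evaluate_against_truth(dec, truth)
  expect_equal(ev_raw$recall[ev_raw$family == "f1_decoy"], 0)
  expect_true(is.na(ev_raw$precision[ev_raw$family == "f1_decoy"]))
  # empty decisions: zero recall for families with truth reads
  ev0 <- evaluate_against_truth(dec[0, ], truth, origin_map = omap)
  expect_equal(ev0$recall, c(0, 0))
  # half of f1 kept: recall 0.5; an origin_map folds decoys to background
  dec2 <- tibble::tibble(read_id = c("r01", "r02", "r16"),
                         family = c("f1", "f1", "f1"))
  ev2 <- evaluate_against_truth(
    dec2, truth,
    origin_map = tibble::tibble(origin = c("f1", "f2"), family = c("f1", "f2")))
  f1 <- ev2[ev2$family == "f1", ]
  expect_equal(f1$tp, 2)
  expect_equal(f1$fp, 1) # the decoy read counts against precision
  expect_equal(f1$recall, 0.4)
  expect_error(evaluate_against_truth(
    tibble::tibble(read_id = "ghost", family = "f1"), truth), "unknown read")
})

test_that("random half-kept decisions recover recall near one half", {
  withr::with_seed(85, {
    truth <- tibble::tibble(read_id = sprintf("r%04d", 1:1000), origin = "f")
    keep <- sample(truth$read_id, 500)
  })
  ev <- evaluate_against_truth(tibble::tibble(read_id = keep, family = "f"), truth)
  expect_equal(ev$recall, 0.5, tolerance = 1e-9)
  expect_equal(ev$precision, 1)
})

test_that("reads and truth survive a FASTQ/TSV round-trip", {
  pl <- tibble::tibble(family = "f", copies = 1L, template_id = "t",
                       template_aa = random_aa(80))
  prof <- community_profile(list(community_member("org", 1, 1000, pl)))
  sim <- simulate_reads(prof, 50, seed = 11)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  expect_equal(read_fastq(fq), sim$reads)
})
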