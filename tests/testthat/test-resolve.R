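test_that("an exact fragment maps at full identity and coverage; the partition is exhaustive", {
  withr::with_seed(51, {
    ref <- tibble::tibble(id = "g", seq = random_nt(900))
    reads <- tibble::tibble(
      id = c("exact", "noise"),
      seq = c(substr(ref$seq, 101, 250), random_nt(150))
    )
  })
  m <- map_reads(reads, ref)
  expect_equal(m$mapped, c(TRUE, FALSE))
  expect_equal(m$pident[1], 100)
  expect_equal(m$coverage[1], 100)
  expect_equal(m$sstart[1], 101L)
  expect_equal(m$send[1], 250L)
  expect_setequal(m$read_id, reads$id)
})

test_that("reverse-complemented fragments map on the minus strand", {
  withr::with_seed(52, {
    ref <- tibble::tibble(id = "g", seq = random_nt(600))
    frag <- substr(ref$seq, 201, 350)
  })
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  m <- map_reads(tibble::tibble(id = "r", seq = rc), ref)
  expect_true(m$mapped)
  expect_equal(m$strand, -1L)
  expect_equal(m$sstart, 201L)
})

test_that("heavily randomized reads do not reach the 50/50 mapping thresholds", {
  withr::with_seed(53, {
    ref <- tibble::tibble(id = "g", seq = random_nt(900))
    reads <- tibble::tibble(
      id = sprintf("r%03d", 1:500),
      seq = vapply(1:500, function(i) {
        mutate_nt(substr(ref$seq, 301, 450), 0.6)
      }, character(1))
    )
  })
  m <- map_reads(reads, ref)
  expect_lte(sum(m$mapped), 5) # >= 99% unmapped
})

test_that("mapping scores agree with a brute-force linear-gap alignment oracle", {
  # oracle: Smith-Waterman, match +1 / mismatch -2 / gap -3 per base,
  # computed via the affine R oracle with open = 0, ext = 3
  nt_mat <- matrix(-2, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                             c("A", "C", "G", "T", "N")))
  diag(nt_mat) <- 1
  nt_mat["N", ] <- -2; nt_mat[, "N"] <- -2
  withr::with_seed(54, {
    for (i in 1:15) {
      ref <- random_nt(300)
      read <- if (i %% 3 == 0) random_nt(80) else
        mutate_nt(substr(ref, 50, 180), 0.1)
      got <- map_reads(tibble::tibble(id = "r", seq = read),
                       tibble::tibble(id = "g", seq = ref))
      fwd <- sw_oracle_score(read, ref, open = 0, ext = 3, mat = nt_mat)
      rcr <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
      rev <- sw_oracle_score(rcr, ref, open = 0, ext = 3, mat = nt_mat)
      expect_equal(got$score, max(fwd, rev), info = paste("case", i))
    }
  })
})

test_that("hao/hdh mapping split sends hdh-derived reads to hdh and hao reads to hao", {
  rs <- benchmark_reference_sets(seed = 7)
  withr::with_seed(55, {
    hdh_gene <- back_translate(mutate_protein(rs$fine$hdh$seq[1], 0.05))
    hao_gene <- back_translate(mutate_protein(rs$fine$hao$seq[1], 0.05))
    mk_reads <- function(gene, prefix, n = 25) {
      tibble::tibble(
        id = sprintf("%s%02d", prefix, 1:n),
        seq = vapply(1:n, function(i) {
          at <- sample(1:(nchar(gene) - 200), 1)
          substr(gene, at, at + 199)
        }, character(1))
      )
    }
    reads <- dplyr::bind_rows(mk_reads(hdh_gene, "hdh"), mk_reads(hao_gene, "hao"))
  })
  split <- split_hao_hdh(reads, rs$hdh_nt)
  expect_equal(nrow(split), nrow(reads))
  acc <- mean(split$class == ifelse(startsWith(split$read_id, "hdh"), "hdh", "hao"))
  expect_gte(acc, 0.95)
  # hao reads fail because their best alignment identity/span is too low
  hao_rows <- split[startsWith(split$read_id, "hao"), ]
  expect_true(all(!hao_rows$mapped | hao_rows$pident < 67 | hao_rows$coverage < 50))
})

test_that("the narG/nxrA second BSR round recovers subset classes and narG", {
  rs <- benchmark_reference_sets(seed = 7)
  withr::with_seed(56, {
    mk_reads <- function(template, prefix, n = 15) {
      gene <- back_translate(mutate_protein(template, 0.05))
      tibble::tibble(
        id = sprintf("%s%02d", prefix, 1:n),
        seq = vapply(1:n, function(i) {
          at <- sample(1:(nchar(gene) - 200), 1)
          substr(gene, at, at + 199)
        }, character(1))
      )
    }
    reads <- dplyr::bind_rows(
      mk_reads(rs$fine$narG$seq[2], "narg"),
      mk_reads(rs$fine$nxrA_A$seq[1], "nxa"),
      mk_reads(rs$fine$nxrA_B$seq[1], "nxb")
    )
  })
  first <- best_hits(search_reads(reads, rs$custom))
  orig <- dplyr::select(first, read_id = qseqid, custom_score = bitscore)
  # all reads entered as the combined family
  expect_true(all(first$family == "narG_nxrA"))
  split <- split_narg_nxra(reads, rs$subsets$nxrA_A, rs$subsets$nxrA_B, orig)
  expect_equal(nrow(split), nrow(reads))
  truth <- dplyr::case_when(
    startsWith(split$read_id, "narg") ~ "narG",
    startsWith(split$read_id, "nxa") ~ "nxrA_A",
    TRUE ~ "nxrA_B"
  )
  expect_gte(mean(split$class == truth), 0.95)
  # second-round ratios match a direct recomputation for a sample of reads
  for (rid in split$read_id[c(1, 20, 40)]) {
    rd <- reads[reads$id == rid, ]
    ha <- best_hits(search_reads(rd, rs$subsets$nxrA_A))
    want <- if (nrow(ha) == 0) NA_real_ else
      ha$bitscore / orig$custom_score[orig$read_id == rid]
    expect_equal(split$ratio_a[split$read_id == rid], want)
  }
  expect_error(split_narg_nxra(reads, rs$subsets$nxrA_A, rs$subsets$nxrA_B,
                               orig[-1, ]),
               "missing original score")
})

test_that("mapping an empty reference set is an error", {
  expect_error(map_reads(tibble::tibble(id = "r", seq = "ACGT"),
                         tibble::tibble(id = character(), seq = character())),
               "empty reference")
})
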