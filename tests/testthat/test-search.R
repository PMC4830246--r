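test_that("six-frame translation follows the standard code, N and strand rules", {
  tf <- translate_six_frames("ATGGCC")
  expect_equal(tf$peptide[tf$frame == 1], "MA")
  tf <- translate_six_frames("ATNGCC")
  expect_equal(tf$peptide[tf$frame == 1], "XA")
  # frame -1 of s equals frame +1 of revcomp(s)
  withr::with_seed(31, s <- random_nt(100))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(translate_six_frames(s)$peptide[4],
               translate_six_frames(rc)$peptide[1])
  # stops appear as '*'
  expect_equal(translate_six_frames("ATGTAA")$peptide[1], "M*")
})

test_that("internal aligner scores equal both brute-force and Biostrings oracles", {
  withr::with_seed(32, {
    for (i in 1:20) {
      q <- random_aa(sample(20:60, 1))
      s <- random_aa(sample(100:300, 1))
      # half the cases share a planted homologous block
      if (i %% 2 == 0) {
        at <- sample(1:(nchar(s) - nchar(q)), 1)
        s <- paste0(substr(s, 1, at - 1), q, substr(s, at + nchar(q), nchar(s)))
      }
      got <- cpp_sw_pair(q, s, 11L, 1L)$score
      expect_equal(got, sw_oracle_score(q, s), info = paste("case", i))
      bio <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
        substitutionMatrix = blosum62_matrix, gapOpening = 11, gapExtension = 1,
        scoreOnly = TRUE)
      expect_equal(got, bio, info = paste("biostrings case", i))
    }
  })
})

test_that("a read carrying an exact reference fragment yields a perfect strong hit", {
  withr::with_seed(33, {
    ref <- tibble::tibble(id = "ref1", seq = random_aa(150), family = "fam")
    frag_aa <- substr(ref$seq, 41, 100) # 60 residues
    reads <- tibble::tibble(id = "r1", seq = back_translate(frag_aa))
  })
  hits <- search_reads(reads, ref)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pident, 100)
  expect_equal(hits$length, 60L)
  expect_lt(hits$evalue, 1e-10)
  expect_equal(hits$sstart, 41L)
  expect_equal(hits$send, 100L)
  expect_equal(hits$family, "fam")
  # same hit found when the read is reverse-complemented
  rc <- tibble::tibble(id = "r1rc",
                       seq = as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString(reads$seq))))
  hits_rc <- search_reads(rc, ref)
  expect_equal(hits_rc$bitscore, hits$bitscore)
  expect_lt(hits_rc$frame, 0)
})

test_that("random reads almost never hit an unrelated database at 1e-6", {
  withr::with_seed(34, {
    db <- tibble::tibble(id = sprintf("s%02d", 1:50),
                         seq = vapply(rep(250, 50), random_aa, character(1)))
    reads <- tibble::tibble(id = sprintf("r%04d", 1:1000),
                            seq = vapply(rep(200, 1000), random_nt, character(1)))
  })
  hits <- search_reads(reads, db, min_query_coverage = 0)
  expect_lte(length(unique(hits$qseqid)), 10)
})

test_that("relaxing the E-value cutoff never removes a read from the hit set", {
  withr::with_seed(35, {
    rs <- make_reference_set("fam", n_targets = 3, n_decoys = 1, length_aa = 120)
    reads <- tibble::tibble(
      id = sprintf("r%02d", 1:30),
      seq = vapply(1:30, function(i) {
        src <- rs$targets$seq[(i - 1) %% 3 + 1]
        at <- sample(1:60, 1)
        mutate_nt(back_translate(substr(src, at, at + 59)), 0.25)
      }, character(1))
    )
  })
  strict <- search_reads(reads, rs$targets, evalue_cutoff = 1e-8)
  loose <- search_reads(reads, rs$targets, evalue_cutoff = 1e-3)
  expect_true(all(unique(strict$qseqid) %in% unique(loose$qseqid)))
  expect_gte(nrow(loose), nrow(strict))
})

test_that("the k-mer prefilter does not change hits for homologous pairs", {
  withr::with_seed(36, {
    rs <- make_reference_set("fam", n_targets = 2, n_decoys = 1, length_aa = 100)
    reads <- tibble::tibble(
      id = sprintf("r%02d", 1:10),
      seq = vapply(1:10, function(i) {
        mutate_nt(back_translate(substr(rs$targets$seq[(i %% 2) + 1], 10, 90)), 0.05)
      }, character(1))
    )
  })
  with_pref <- search_reads(reads, rs$targets)
  no_pref <- search_reads(reads, rs$targets, min_kmer_hits = 0)
  expect_equal(with_pref$qseqid, no_pref$qseqid)
  expect_equal(with_pref$bitscore, no_pref$bitscore)
  expect_equal(with_pref$sseqid, no_pref$sseqid)
})

test_that("best_hits applies the score, E-value, subject-id tie-break", {
  hits <- tibble::tibble(
    qseqid = c("r1", "r1", "r1", "r2", "r2"),
    sseqid = c("b", "a", "c", "z", "y"),
    bitscore = c(100, 100, 90, 80, 80),
    evalue = c(1e-20, 1e-20, 1e-15, 1e-9, 1e-10)
  )
  best <- best_hits(hits)
  expect_equal(best$sseqid[best$qseqid == "r1"], "a")
  expect_equal(best$sseqid[best$qseqid == "r2"], "y")
})

test_that("external tabular hits reproduce internal search results", {
  withr::with_seed(37, {
    rs <- make_reference_set("fam", n_targets = 3, n_decoys = 1, length_aa = 120)
    reads <- tibble::tibble(
      id = sprintf("r%02d", 1:15),
      seq = vapply(1:15, function(i) {
        mutate_nt(back_translate(substr(rs$targets$seq[(i %% 3) + 1], 5, 115)), 0.03)
      }, character(1))
    )
  })
  internal <- search_reads(reads, rs$targets)
  path <- withr::local_tempfile(fileext = ".tab")
  write_alignment_tab(internal, path)
  external <- search_reads(reads, rs$targets, scorer = "external", hits = path)
  expect_equal(external$qseqid, internal$qseqid)
  expect_equal(external$bitscore, internal$bitscore)
  expect_equal(best_hits(external)$sseqid, best_hits(internal)$sseqid)
  # unknown read ids are rejected
  bad <- internal
  bad$qseqid[1] <- "ghost"
  expect_error(search_reads(reads, rs$targets, scorer = "external", hits = bad),
               "unknown read id")
})
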