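simple_tax <- function() {
  taxonomy_table(tibble::tibble(
    taxid = c("root", "F", "gA", "gB", "gC", "G", "gD"),
    parent = c("root", "root", "F", "F", "F", "root", "G"),
    rank = c("root", "family", "genus", "genus", "genus", "family", "genus"),
    name = c("root", "famF", "genusA", "genusB", "genusC", "famG", "genusD")
  ))
}

subject_taxa <- tibble::tibble(
  sseqid = c("sA", "sB", "sC", "sD"),
  taxid = c("gA", "gB", "gC", "gD")
)

test_that("taxonomy validation enforces a single root and rejects cycles", {
  expect_error(taxonomy_table(tibble::tibble(
    taxid = c("a", "b"), parent = c("a", "c"), rank = "x", name = "y"
  )), "missing")
  expect_error(taxonomy_table(tibble::tibble(
    taxid = c("a", "b", "c"), parent = c("a", "c", "b"), rank = "x", name = "y"
  )), "cycle")
  expect_error(taxonomy_table(tibble::tibble(
    taxid = c("a", "b"), parent = c("a", "b"), rank = "x", name = "y"
  )), "exactly one root")
})

test_that("single hits map to their own taxon; sibling genera collapse to the family", {
  hits1 <- tibble::tibble(qseqid = "r1", sseqid = "sA", bitscore = 100)
  out <- assign_lca(hits1, simple_tax(), subject_taxa)
  expect_equal(out$taxid, "gA")
  hits2 <- tibble::tibble(qseqid = "r2", sseqid = c("sA", "sB"),
                          bitscore = c(100, 100))
  out <- assign_lca(hits2, simple_tax(), subject_taxa)
  expect_equal(out$taxid, "F")
  expect_equal(out$name, "famF")
})

test_that("the 90% score filter excludes weak hits before the LCA", {
  # scores 100 (genus A), 95 (genus B), 89 (genus C): 89 < 90 is excluded,
  # so the result is LCA(A, B) = family F, not root
  hits <- tibble::tibble(qseqid = "r", sseqid = c("sA", "sB", "sC"),
                         bitscore = c(100, 95, 89))
  out <- assign_lca(hits, simple_tax(), subject_taxa)
  expect_equal(out$taxid, "F")
  # with genus D (other family) at 95 the LCA would cross to the root
  hits2 <- tibble::tibble(qseqid = "r", sseqid = c("sA", "sD"),
                          bitscore = c(100, 95))
  expect_equal(assign_lca(hits2, simple_tax(), subject_taxa)$taxid, "root")
  # strict threshold: a hit at exactly 90 is excluded unless inclusive = TRUE
  hits3 <- tibble::tibble(qseqid = "r", sseqid = c("sA", "sD"),
                          bitscore = c(100, 90))
  expect_equal(assign_lca(hits3, simple_tax(), subject_taxa)$taxid, "gA")
  expect_equal(assign_lca(hits3, simple_tax(), subject_taxa,
                          inclusive = TRUE)$taxid, "root")
})

test_that("candidates are truncated to max_hits after the score filter", {
  tax <- simple_tax()
  hits <- tibble::tibble(qseqid = "r",
                         sseqid = c("sA", "sB", "sD"),
                         bitscore = c(100, 99, 98))
  out <- assign_lca(hits, tax, subject_taxa, max_hits = 2)
  expect_equal(out$taxid, "F") # sD truncated away
})

test_that("a subject without a taxonomy mapping is an error", {
  hits <- tibble::tibble(qseqid = "r", sseqid = "ghost", bitscore = 10)
  expect_error(assign_lca(hits, simple_tax(), subject_taxa), "without taxonomy")
})

test_that("LCA agrees with the brute-force oracle on random taxonomies and hit sets", {
  withr::with_seed(61, {
    for (case in 1:300) {
      tax <- random_taxonomy(sample(5:40, 1))
      nsub <- sample(2:8, 1)
      st <- tibble::tibble(sseqid = paste0("s", 1:nsub),
                           taxid = sample(tax$taxid, nsub, replace = TRUE))
      nh <- sample(seq_len(min(6, nsub)), 1)
      hits <- tibble::tibble(qseqid = "r",
                             sseqid = sample(st$sseqid, nh, replace = FALSE),
                             bitscore = round(runif(nh, 50, 100), 1))
      got <- assign_lca(hits, tax, st)
      # oracle: same candidate rule, independent LCA computation
      top <- max(hits$bitscore)
      cand <- hits[hits$bitscore > 0.9 * top, ]
      cand <- cand[order(-cand$bitscore, cand$sseqid), ][seq_len(min(5, sum(hits$bitscore > 0.9 * top))), ]
      want <- lca_oracle(st$taxid[match(cand$sseqid, st$sseqid)], tax)
      expect_equal(got$taxid, want, info = paste("case", case))
      # invariant: the result is an ancestor of every candidate
      parent <- stats::setNames(tax$parent, tax$taxid)
      for (tid in st$taxid[match(cand$sseqid, st$sseqid)]) {
        anc <- tid
        repeat {
          if (anc == got$taxid) break
          if (parent[[anc]] == anc) break
          anc <- parent[[anc]]
        }
        expect_equal(anc, got$taxid)
      }
    }
  })
})

test_that("taxon summaries collapse rare groups to 'other' and sum to one", {
  asg <- tibble::tibble(
    dataset = rep(c("PA2", "PA5"), c(1000, 1000)),
    group = c(rep("A", 700), rep("B", 295), rep("rare", 5),
              rep("A", 500), rep("B", 496), rep("rare", 4))
  )
  out <- summarize_taxa(asg, min_fraction = 0.01)
  expect_false("rare" %in% out$group)
  expect_true("other" %in% out$group)
  sums <- tapply(out$fraction, out$dataset, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)
  # a group over the threshold in one dataset is reported in both
  asg2 <- tibble::tibble(
    dataset = rep(c("d1", "d2"), c(100, 1000)),
    group = c(rep("X", 98), rep("Y", 2), rep("X", 995), rep("Y", 5))
  )
  out2 <- summarize_taxa(asg2, min_fraction = 0.01)
  expect_true(all(c("X", "Y") %in% out2$group[out2$dataset == "d1"]))
  expect_equal(out2$fraction[out2$dataset == "d2" & out2$group == "Y"], 0.005)
})

test_that("all reads in one taxon give fraction 1", {
  out <- summarize_taxa(tibble::tibble(group = rep("A", 10)))
  expect_equal(out$fraction, 1)
})
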