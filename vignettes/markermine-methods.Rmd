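---
title: "Marker-gene mining with two-database BLAST-score-ratio screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gene mining with two-database BLAST-score-ratio screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markermine)
library(dplyr)
```

## The problem

Read-based functional profiling of a metagenome asks, for each sequencing
read, whether it comes from a marker gene of interest — a nitrogenase
subunit (*nifH*), a nitrite reductase (*nirS*, *nirK*), a hydrazine synthase
(*hzsA*), and so on. A translated search of reads against a small curated
protein database answers this cheaply, but with a catch: at a permissive
E-value, reads from *homologs outside the target family* also hit the
database. A nitrate reductase read hits a nitrite oxidoreductase database
because *narG* and *nxrA* descend from one molybdopterin oxidoreductase;
formate dehydrogenase reads hit both. Tightening the E-value does not fix
this — it throws away the *divergent true positives* that make metagenome
mining worthwhile in the first place, the novel lineages not yet in any
database.

markermine implements a screening strategy built around a two-database
**bit score ratio (BSR)**. Each read with a hit to the curated marker
database is also searched against a large background database (NR, or a
decoy stand-in), and the statistic

$$ r = \frac{S_\text{custom}}{S_\text{background}} $$

(both bit scores) drives the keep/discard decision with a per-family cutoff
$c$: keep iff $r \ge c$, or if no background hit exists at all. The logic:
a read from a *known off-target* organism has a near-perfect background hit
and a mediocre custom hit, so $r$ is small; a read from a *novel* member of
the target family has a mediocre hit to both databases, so $r$ stays near
or above 1 and the read survives. Reads with no background hit at all are
kept as true positives by the same reasoning.

Around this statistic the package provides the full pipeline: quality
trimming, translated search, per-family decisions, second-stage resolution
of the homolog pairs *hao*/*hdh* and *narG*/*nxrA*, lowest-common-ancestor
(LCA) taxonomy, normalization of counts to the single-copy *rpoB* gene, a
detection-limit abundance estimator, and reference-guided iterative
reconstruction of (near) full-length genes. A synthetic-community
simulator with per-read ground truth makes every stage testable.

## Quality trimming and read filters

`trim_reads()` reproduces the modified-Mott end trimming used by common
workbenches: each base contributes a score $\ell - p_i$ where
$p_i = 10^{-Q_i/10}$ is its Phred error probability and $\ell$ is the
quality limit (default 0.05). The retained region is the contiguous
subsequence with maximal score sum, found exactly; ties are resolved
leftmost-first, then longest, so trimming is deterministic and idempotent.
A read whose bases are all worse than the limit trims to empty. The exact
trimming algorithm of the original commercial workbench is proprietary;
the maximal-scoring-subsequence formulation here is the documented
equivalent and is verified in the test suite against an $O(n^2)$
brute-force oracle.

`filter_reads()` then applies the whole-read criteria: length at least
100 bp (inclusive — the boundary read is kept) and at most 2 ambiguous
bases. The ambiguity rule is applied as a post-trim whole-read filter;
filter semantics are order-stable and reproducible, which trimming-based
interpretations of an "allowed ambiguities" setting are not.

## The translated search

`search_reads()` is the BLASTx-equivalent screen: every read is translated
in six frames (standard code; codons containing N become `X`, stops `*`)
and aligned against the protein reference set by Smith–Waterman with
BLOSUM62 scores and affine gaps (open 11, extend 1). Bit scores and
E-values follow the Karlin–Altschul form with the published
gapped-BLOSUM62 constants ($\lambda = 0.267$, $K = 0.041$); the search
space is frame length × database residues. Exact parity with NCBI BLAST
E-values is *not* promised and not needed: the decision statistic is a
ratio of bit scores computed under one scheme, and the E-value cutoff
(default $10^{-6}$) is permissive. A shared amino-acid 4-mer prefilter
(default: at least 2 shared 4-mers) limits the quadratic alignment work to
plausible pairs; `min_kmer_hits = 0` disables it and brute-forces every
pair, which the tests use to confirm the prefilter changes nothing for
homologous hits. Per (read, subject) pair only the single best-scoring HSP
is kept — at read lengths around 230 bp, HSP tiling has nothing to add.

Two deliberate conventions:

* **Hit coverage.** A hit must span at least 50% of the read
  (`min_query_coverage = 0.5`). The pipeline's truth notion — both in the
  read-extraction mappings and in the simulator below — is "the
  read lies at least half inside the gene", and the operating rule is
  chosen to match the definition of what counts as a marker read. Without
  it, reads straddling a gene boundary with 30–49% overlap are detected
  but can never be "true", distorting every precision estimate. Set it to
  0 for raw BLASTx-like behaviour.
* **Coordinates.** Query coordinates are always reported on the forward
  strand with `qstart <= qend`; the aligned strand is the sign of the
  `frame` column. This keeps the 12-column tabular convention
  (`read_alignment_tab()` / `write_alignment_tab()`) round-trippable and
  unambiguous.

`search_reads(scorer = "external")` ingests a 12-column tabular file from
an external aligner instead; the tests confirm both routes give identical
downstream decisions when fed equivalent tables.

## BSR decisions

`compute_bsr()` forms the per-read ratio from the best custom and best
background hits (ties broken by E-value, then subject id — fully
deterministic), and `apply_cutoff()` applies the per-family, per-dataset
cutoffs. The packaged `table1_cutoffs()` carries the per-family defaults
(e.g. *narG* 0.5, *nirK* 0.55, *nirS* 0.6, *norB/norZ* 0.8, *nosZ*
0.8/0.75, *hzsA* 0.75, *nxrA* 0.85). Decisions are boundary-inclusive
($r \ge c$ keeps): strict vs inclusive keeping is
underdetermined, so the inclusive convention was chosen and is documented here.
Families marked `manual` — small reference sets screened by eye in the
manual-review workflow — get `flagged_manual`; `export_manual_review()` writes
them to TSV and `apply_cutoff(keep_list = ...)` replays a completed review
as data, making the manual step reproducible. `plot_bsr_scatter()` and
`plot_bsr_histogram()` reproduce the familiar diagnostic: a clean screen
shows a bimodal ratio histogram with the cutoff in the valley.

Reads hitting several families are assigned to the family of their single
best custom hit before the ratio is formed: one decision per read.

## Homolog resolution

Two marker pairs need a second stage.

* ***hao* / *hdh***: reads kept by the combined family are mapped
  (`map_reads()`) against reference *hdh* nucleotide copies under the
  CLC-style thresholds — local alignment with match +1, mismatch −2,
  indel −3 per base, both strands, mapped iff identity ≥ 50% over a span
  ≥ 50% of the read. Mapped reads are *hdh*, unmapped *hao*
  (`split_hao_hdh()`). Note the scoring scheme makes the span condition
  the sharp one: a full-span alignment needs local identity above ~2/3,
  which *hao* reads against *hdh* references do not reach.
  "Identity" here is computed over the alignment columns and the span
  over the read — the workbench's length-fraction/similarity semantics;
  the alternative (identity over the whole read) is not used.
* ***narG* / *nxrA*** (`split_narg_nxra()`): kept reads are re-searched
  against two *nxrA* subset databases (the Nitrobacter-type and the
  Nitrospira/Nitrospina/anammox-type lineages); the second-round ratio of
  best-subset score to the read's original combined-database score decides
  — ratio ≥ 0.85 against a subset assigns that subset's *nxrA* class,
  otherwise *narG*. A read above the cutoff against both subsets goes to
  the higher ratio; an exact tie is flagged `ambiguous` rather than
  silently resolved. The 0.85 default is the documented operating point;
  the reported working range extends to 0.95 and the parameter is exposed.

Both splits are exhaustive, exclusive partitions of their input, which the
tests assert directly.

## LCA taxonomy

`assign_lca()` implements the MEGAN-style rule: candidates are the hits
with bit score strictly over 90% of the read's top score, truncated to the
best 5 (ties by subject id, the top hit counting as one of the five), and
the read is assigned the lowest common ancestor of the candidates' taxa.
"Over 90%" is read as strict; `inclusive = TRUE` flips the convention.
The top hit always qualifies, so every read with a hit is assigned.
`summarize_taxa()` reports per-group read fractions and collapses groups
below 1% of the community in every dataset into `other`, the reporting
rule used for community overviews. Agreement with a brute-force
ancestor-path oracle is tested on 1,000 random taxonomies.

## Abundance and the detection limit

`normalize_count()` is reads per kilobase of gene per million metagenome
reads:

$$ \tilde{c} = \frac{c \times 1000 \times 10^6}{L_\text{gene} \times N_\text{total}} $$

`fraction_of_rpob()` divides a family's normalized count by normalized
*rpoB*. Because *rpoB* is universal and single-copy, its normalized count
estimates per-genome sequencing depth, and the fraction estimates the
proportion of genomes carrying the marker. No copy-number correction is
applied — multi-copy families (e.g. *hao*, with up to ten paralogs per
genome) can legitimately exceed 1, and this is a documented caveat, not an
error. Per-family gene lengths default to the median ungapped reference
length (`reference_gene_lengths()`, amino acids × 3) when true per-family
lengths are unknown; an override column takes precedence
when true lengths are known.

`estimate_detection_abundance()` answers "how abundant could a carrier
population be, given how few reads we saw?": with expected reads
$E = (L_\text{gene}/L_\text{genome}) \times N_\text{total}$, it reports
$E$, the fold-depletion $E/c$ and the abundance estimate $100\,c/E$.
With the defaults (900 bp gene, 3 Mbp genome) and a 1.6-million-read
library, 3 observed *nifH* reads give $E = 480$ (3 per 10,000 sequenced
reads), 160-fold depletion, and an abundance of 0.625%, printed as 0.6%
at one decimal.

## Iterative reconstruction

`iterative_reconstruct()` grows a gene sequence from reads seeded by a
related reference: map all reads to the current consensus, replace each
covered column by the majority base of the pileup (ties in fixed order
A < C < G < T; uncovered columns keep the previous base), optionally extend
the ends by column-majority over reads overhanging at least 20 bp, and
repeat. Because the mapped set is not guaranteed monotone, convergence is
declared when the mapped read-id set equals *any* previously seen set
(cycle-safe); the round limit (default 20) is a backstop. The per-gene
mapping parameters follow the per-gene defaults: 50% identity / 50% span for
*hdh*, 80/50 for close *nxrA* relatives, 30/50 with mismatch penalty 1 for
divergent novel lineages. End extension beyond the seed is optional
(`extend = FALSE` restricts the consensus to the seed footprint). With no
mappable reads the seed is returned unchanged, flagged converged.

## The synthetic benchmark: what it emulates, and what it does not

All quantitative claims about the pipeline are made on simulated
communities with known truth, because station-level results on the real
metagenomes require the full read sets and NCBI-NR. The simulator is first-class,
tested code:

* `make_reference_set()` builds a marker family as targets around a random
  protein ancestor, plus **decoys** — targets mutated by point substitution
  at a set divergence (default 0.4, i.e. ~60% identity) — that populate the
  background database, standing in for NR's off-target homologs.
* `community_profile()` / `simulate_reads()` draw reads from member
  genomes proportionally to abundance × genome size, uniform positions,
  random strand; lengths are normal (mean 230 bp, sd 30, clamped to
  100–300 bp, a desk-scale stand-in for ~330 bp single-end
  libraries); errors are i.i.d. substitutions (default 1%) plus rare 1-bp
  indels (default one-twentieth of the substitution rate); base qualities
  encode the substitution rate with small jitter. A read's truth origin is
  the family whose gene covers ≥ 50% of it. Marker templates are stored as
  amino acids and back-translated with uniformly random synonymous codons,
  so reference and community genes differ at silent sites — the screen
  under test is a translated search and must not be rewarded for DNA-level
  identity.
* `benchmark_reference_sets()` / `benchmark_profile()` define the default
  two-station benchmark: a suboxic, nitrifier-leaning community and an
  anoxic-core, anammox-heavy community, seven screening families including
  both homolog pairs, every cellular member carrying one *rpoB*, decoy
  carriers at a few percent abundance, and a neutral background fraction.
  Decoy-carrying members embed the decoy sequence *verbatim*: false
  positives in the real workflow are reads from database-known organisms,
  which is exactly why their background hit is near-perfect. Target
  members instead carry templates at 5% divergence from a reference
  target — novel-but-related lineages, the reads the method exists to
  keep. Genomes are 30 kb stand-ins; *rpoB* fractions are genome-size
  invariant (read sampling ∝ abundance × genome size cancels genome size),
  so this only scales runtime, not estimates.

Problem sizes used by the tests and the acceptance script: 2 × 25,000
benchmark reads, a 10,000-read run for the decision-oracle comparison,
100,000 reads for *rpoB*-fraction recovery, 1,000 random taxonomies for
the LCA oracle, 200 random reads for the trimmer oracle, and 20×
error-free coverage for reconstruction. At the benchmark's reference
seeds the screen reaches ≥ 0.95 precision and recall per family, ≥ 0.95
split accuracy for both homolog pairs, exact agreement with the
brute-force decision oracle, and *rpoB* fractions within 3 binomial SDs
of the true carrier fractions.

What passing these tests does **not** show: platform-realistic error
structure (no Ion Torrent homopolymer model — the pipeline, not the
platform, is under test), real reference-database curation artifacts,
chimeras, strain microheterogeneity, or NR's actual composition. The decoy
background is a structured stand-in, not a 200-million-sequence database.

## Numerical choices and degenerate inputs

* All tie-breaks are fixed and documented: best hits by bit score, then
  E-value, then subject id; majority bases in A < C < G < T order; trim
  segments leftmost-then-longest; equal second-round ratios flagged.
* Cutoff boundaries are inclusive; the LCA score threshold is strict.
* Parsers are strict — wrong column counts, non-numeric fields, duplicate
  ids, quality/sequence length mismatches are errors with line numbers,
  never silent coercion.
* Degenerate inputs have defined behaviour: empty trim results are
  allowed; empty read sets return empty tibbles; an empty reference set,
  a missing cutoff, a subject without taxonomy, zero *rpoB* are errors
  with instructive messages; `observed = 0` gives an infinite
  fold-depletion sentinel and 0% abundance.

## Known limitations

* The decoy divergence of the benchmark (0.4) puts the false-positive
  ratio mode near 0.53 ± 0.08, close above the lowest packaged cutoff
  (*narG/nxrA* at 0.5). That family's benchmark precision therefore sits
  near its acceptance margin (~0.94–0.96 across simulation seeds) — an
  intrinsic property of screening 60%-identity decoys at a 0.5 cutoff,
  and a useful reminder that per-family cutoffs must be placed against
  the *observed* ratio distribution (`plot_bsr_histogram()`), which is
  how such cutoffs are calibrated in practice.
* Because the benchmark draws its marker families at random, the
  realized distance between the hao/hdh sub-lineages varies between
  reference-set seeds, and with it the hao/hdh mapping-split accuracy
  (roughly 0.89–0.99 across seeds; the sub-ancestor divergence of 0.25
  puts mean cross identity near the mapper's span-positive threshold).
  Real reference sets have a fixed, known divergence and do not carry
  this sampling variability.
* E-values are internally consistent but not NCBI-BLAST-identical (word
  size and composition adjustments are not modelled; version-dependent
  constants are irrelevant to a ratio statistic and documented as such).
* The internal aligner is a desk-scale screener for ~10^4–10^5 reads
  against curated sets, not a general-purpose search engine; for larger
  jobs run an external aligner and feed the tabular output through
  `scorer = "external"`.
* LCA "min support" and "top percent by alignment" MEGAN variants are out
  of scope, as are de novo assembly and phylogenetic tree placement.
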