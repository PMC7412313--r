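---
title: "Detecting graft-mobile mRNAs from heterograft RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting graft-mobile mRNAs from heterograft RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftmobile)
```

## The problem

In an interspecies heterograft — a shoot (scion) of one species grafted onto
the rooted stock of another — some mRNAs synthesized in the scion travel
through the phloem and can be detected in rootstock tissue. Sequencing RNA
from the rootstock therefore yields a mixture: an overwhelming majority of
rootstock transcripts and a trace of scion-derived ("mobile") transcripts.
Because the two species' transcriptomes are diverged (here ~4% at the
nucleotide level, i.e. ~96% identity), reads can in principle be assigned to
their species of origin — but only with careful control of alignment
tolerances, sequencing error, and shared/identical sequence between the
genomes.

`graftmobile` implements the discovery analysis as a tested pipeline:

1. **Read QC** — adapter trimming, sliding-window quality clipping, discard
   of trimmed reads shorter than 40 bases, and removal of read pairs
   matching a ribosomal RNA reference within 3 mismatches.
2. **Classification cascade** — each surviving pair is tested in a fixed
   order: (a) if it aligns as a proper pair to the *rootstock*
   transcriptome within **2 edits** per mate it is endogenous; (b) else, if
   either mate **perfectly matches** a read from non-grafted control plants
   it is discarded as indistinguishable background; (c) else, if it aligns
   as a proper pair to the *scion* transcriptome within **1 edit** per mate
   it is **transmitted**; (d) otherwise it is unassigned.
3. **Replicate-supported calling** — a scion transcript is called mobile
   under a growth condition when transmitted pairs support it in at least
   **2 of 3** biological replicates. Abundance is reported as RPKM
   (`1e9 * count / (length * total mapped fragments)`).
4. **Cross-system comparison** — reciprocal-best-hit (RBH) orthology at
   E < 1e-5 to translate ids between systems, covered percentages
   (`100 k / K`), exact hypergeometric over-/under-enrichment tests, and
   2-4-way Venn partitions of per-condition mobile sets.

The asymmetric edit caps encode the biology: the rootstock stage is
permissive (2 edits) so that endogenous reads with sequencing errors are
captured even imperfectly, while the scion stage is strict (1 edit) so that
a transmitted call requires a near-perfect cross-species match. At 4%
divergence an 85-bp read from one species carries on average ~3.4
mismatches against the other, so the homologous transcript rarely satisfies
either cap for the wrong species.

## The aligner

The cascade's alignments use a from-scratch k-mer-seeded banded
edit-distance aligner (`build_index()`, `align_read()`, `align_pairs()`)
rather than an external mapper, so that every mapping step has an explicit,
oracle-testable contract at desk scale:

* Edit distance is Levenshtein (substitutions + insertions + deletions),
  end-to-end in the read — the caps count edits across the whole read, not
  a local fragment.
* The reference is indexed at every position congruent to 0 mod `step`
  (default 5) with `k = 15`-mers. A read of length L with e edits contains
  an exact clean segment of length at least `ceiling((L - e)/(e + 1))`;
  a clean segment of length `k + step - 1 = 19` always contains an indexed
  k-mer. For 85-bp reads with e <= 2 the clean segment is at least 28, so
  seeding provably loses no qualifying placement at the caps the cascade
  uses.
* Seed hits are grouped by implied diagonal; every candidate start within
  `max_edit` of a seed diagonal is verified by banded dynamic programming
  (band half-width = `max_edit`, exact for distances <= `max_edit`). All
  placements within the cap are reported, sorted by
  (edit distance, target, start).
* A pair is *proper* when both mates hit the same target on opposite
  strands with an implied insert (outermost span) inside `insert_bounds`
  (default 50-600 bp). Among qualifying placements the minimal summed edit
  wins; ties are broken by target id then leftmost start, and all targets
  tied at the minimum are recorded (`ambiguous = TRUE` when more than one;
  ambiguous transmitted pairs count toward detection of every tied target,
  a conservative presence/absence choice).

The test suite holds the aligner to an independent brute-force oracle:
`utils::adist` Levenshtein distances over *all* placements and segment
lengths must agree exactly with the seeded implementation on a thousand
random instances.

## The synthetic experiment generator

Raw sequencing data for a real heterograft is not shipped; instead
`simulate_experiment()` generates a ground-truth experiment with the
statistical structure the analysis assumes:

* **References.** An ancestral transcript set (default 300 transcripts,
  500-2000 bp) is diverged into scion and rootstock lineages by independent
  per-site substitutions. The per-lineage rate is solved from
  `pairwise = 2r - (4/3) r^2` so the expected *between-lineage* divergence
  equals `divergence` (default 0.04) without bias; the naive
  "half the rate per lineage" approximation would undershoot by ~2%
  relative, because independent mutations can coincide at a site.
* **Coding structure.** By default transcripts are open reading frames
  (ATG, stop-free sense codons, terminal stop); substitutions that would
  create a premature stop are redrawn among the remaining alternatives and
  indels are whole codons — a purifying-selection-like model. Random iid
  sequences would truncate naive translations at ~20 residues on average
  and make proteome-level orthology degenerate, which is unrealistic for
  the curated proteomes RBH analyses actually use.
* **Truth sets.** Mobile transcripts are drawn as disjoint Venn regions
  over the four conditions (full nutrition, low N, low P, low Fe). The
  default structure (`default_truth_regions()`: a 28-transcript core mobile
  everywhere, 15/11/14 condition-specific transcripts, small two-way
  overlaps; union 80 of 300) mirrors, at desk scale, the qualitative
  pattern of a real experiment in which roughly a third of the union is
  mobile under every condition and each starvation induces its own
  minority.
* **Reads.** 85-bp stranded pairs (mate 1 sense, mate 2 antisense of the
  fragment 3' end, dUTP-like), inserts uniform in 150-400 bp, per-base
  substitution error 0.005, Poisson depth 30 pairs per rootstock
  transcript. Mobile scion transcripts are sampled at
  `depth * mobile_abundance_factor` (default 0.7, i.e. depth 21) — below
  endogenous abundance, as arriving transcripts are a trace component, yet
  deep enough that per-replicate detection is expected. The abundance of
  mobile mRNAs in root tissue is not an empirically constrained quantity;
  this is a declared free parameter of the simulation.
* **Nuisance signal.** A fraction of pairs (2%) has short inserts that read
  through into the 3' adapter (followed by G homopolymer, as on
  two-channel instruments); 5% of mates carry a low-quality 3' tail; rRNA
  contaminant pairs are injected at 2% from a separate rRNA reference.
  Non-grafted control samples are generated by the same machinery with no
  scion transcripts.
* **Bookkeeping.** Every read name records its source transcript, origin
  class (rootstock/scion/rrna), condition and replicate, so recall and
  precision of the final calls are measurable exactly. Each sample's RNG
  seed is derived deterministically from
  (master seed, condition, replicate, grafted), so identical configurations
  reproduce byte-identical samples.

What the generator does **not** emulate: splice isoforms, PCR duplicates,
GC and positional coverage bias, quality-score decay along the read,
paralogous gene families, and incomplete reference annotation. Passing the
truth-recovery tests therefore shows the cascade's logic is correct under
the stated error model, not that real-data recall would be 100%: on real
tissue, reference incompleteness and shared identical regions between
species dominate the error budget. The perfect-match control subtraction
stage, in particular, is nearly inert in simulation (reads escaping the
rootstock stage carry errors and rarely match a control read exactly); in
real data it removes background from unannotated or identical genomic
regions, which the simulation does not model. Its contract is covered by
constructed unit tests instead.

## Statistical components

* `hypergeom_test(k, K, n, N)` computes both one-sided exact tails by
  log-binomial accumulation over the support; the reported direction is the
  smaller tail and the reported p is `min(p_over, p_under)` (the two tails
  share the point mass at `k`, so their sum is at least 1). The **universe
  size N is a required, explicit argument**: for within-system analyses the
  scion reference size is the natural choice, for cross-system comparisons
  the number of established ortholog pairs. Published tables of this kind
  typically omit N, which is why printed p-values cannot generally be
  reproduced and why the package refuses to guess.
* `covered_percent(k, K)` rounds half-up to two decimals, matching the
  printed-table convention; all table cells used in validation are robust
  to half-even versus half-up.
* The internal protein scorer (`score_pair()`, `rbh_orthologs()`) is plain
  Smith-Waterman with affine gaps (BLOSUM62, open 11, extend 1) plus
  Karlin-Altschul ungapped constants (lambda = 0.3176, K = 0.134) for bit
  scores and an approximate e-value `m * db_size * 2^(-bit)`. These
  statistics exist to rank hits for RBH on synthetic proteomes without an
  external search tool; they are not a re-implementation of a search
  engine's composition-adjusted statistics. The primary input path for real
  analyses remains precomputed 12-column tabular hit files (`load_hits()`).
  Best hits use strict `E < cutoff`, ties broken by bit score, then
  e-value, then lexicographically smallest subject — fully deterministic.
* Isoform-suffix normalization (`strip_isoform_suffix()`) is available but
  off by default: correspondence is carried at the id level of the provided
  sequences.

## Numerical and degenerate-input choices

* Quality trimming cuts at the *start* of the first width-4 window whose
  mean Phred quality drops below 20 (Trimmomatic-style); the published
  description quantifies neither, so these are declared defaults, not
  inferred values.
* Adapter trimming takes the leftmost (longest-overlap) suffix match within
  a 10% mismatch fraction, minimum overlap 3.
* The rRNA filter is substitutions-only (Hamming, no indels) over every
  offset and strand, per its mismatch-cap contract; a pair is dropped when
  either mate matches, preserving pair integrity. The seeded implementation
  (pigeonhole chunks, exact 10-mer seeds) is exactly equivalent to the
  brute scan and is tested against it.
* `k = 0` overlaps render direction and p-value as `NA` in
  `enrichment_report()` — the degenerate "nothing shared" cells.
* Empty rRNA sets, empty control sets, empty hit files, and empty truth
  regions are identities, not errors; reads shorter than `k` produce a
  warning and an empty result.

## Problem sizes used in validation

The shipped tests and the acceptance script validate at desk scale chosen
as the package's own study conditions: 300 + 300 transcripts, 4 conditions
x 3 replicates plus 3 non-grafted controls (~150,000 read pairs total),
divergence 0.04, error rate 0.005, mobile depth 21; 1000 random
aligner-versus-oracle instances; the full hypergeometric grid to N = 12;
RBH recovery on the 300-protein synthetic proteomes. Against the simulated
truth the pipeline attains recall and precision of 1.0 per condition and
RBH recovers all 300 ortholog pairs with none false — values the test suite
asserts as >= 0.90 / >= 0.95 and >= 0.99 / zero-false respectively, since
they are stochastic under reseeding.

## Known limitations

* Transcript-level references: the original analyses aligned to genomes
  with splice-aware mappers; here classification logic is exercised against
  transcript sequences, which changes nothing about the cascade's decision
  structure but ignores intronic and intergenic placements.
* Mobile-transcript integrity (full-length arrival) is not assessed —
  presence/absence calling only.
* No differential-abundance statistics between conditions; RPKM is
  descriptive.
* The internal e-values are approximations; for publication-grade orthology
  use a real search engine's tabular output as input.
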