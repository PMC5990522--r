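---
title: "Clonal architecture and mutation order from targeted single-cell DNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal architecture and mutation order from targeted single-cell DNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

clonetrace analyses targeted amplicon sequencing of single tumor cells: a
patient-specific panel of somatic events plus shared heterozygous germline
SNPs, amplified from each single-cell genome, giving one ref/alt read-depth
pair per (cell, locus). This vignette explains the models behind each
stage, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the design choices made where the design was
genuinely open.

## Data model and error processes

Whole-genome amplification of a single cell is uneven. Three error
processes dominate targeted single-cell data and drive every modelling
choice in the package:

* **Locus drop-out (LDO).** A locus fails to amplify; few or no reads.
  Measured as the fraction of germline SNPs with fewer than 4 reads.
* **Allelic drop-out (ADO).** Only one of the two alleles amplifies, so a
  heterozygous site reads (near-)homozygous. Measured at covered SNPs as a
  minor-allele fraction below `minor_frac = 0.10`; at that threshold,
  ordinary amplification imbalance at 4+ reads is separated from true
  mono-allelic amplification.
* **False-positive reads.** A small number of alternate reads leak into a
  locus the cell does not carry (index hopping, polymerase error,
  cross-contamination during amplification).

QC operates on the germline heterozygous SNPs only — they are heterozygous
in every cell by construction, so any apparent homozygosity is an
amplification artifact. The combined drop-out rate is the per-SNP union
(each SNP counted once; LDO takes precedence because ADO is undefined below
`min_reads`), and cells with a combined rate of one third or more are
removed. The cutoff is applied strictly (`< 1/3`).

Genotype calling is deliberately conservative in both directions: below
`min_total = 10` reads a call is *missing* (no data), and a *present* call
requires both `min_alt = 2` alternate reads and VAF at least
`min_vaf = 0.10`, because a single read is indistinguishable from
amplification error. The resulting per-call error rates under the default
simulation noise are roughly 1% false-present (about half of the leakage
events pass the presence thresholds) and 7% false-absent (half of a 10% ADO
rate collapses to the reference allele, plus borderline-depth calls); these
two numbers anchor the α and β defaults used downstream.

## Clonal deconvolution

The distance between two cells is the Jaccard distance between their
present-event sets, restricted to events observed in both
(pairwise-complete). Two cells with no present events among their shared
informative events are identical (distance 0); cells sharing no informative
events get distance 1 and a flag, so clustering always completes.
Average-linkage agglomeration builds the dendrogram; average linkage is the
standard companion to Jaccard on sparse binary data and is robust to the
one-to-two-cell clusters that real samples contain.

The dendrogram alone, however, cannot reliably resolve nested subclones
that differ by one or two events: at a 7% false-absent rate the expected
Jaccard distance between two cells of the *same* clone (≈ 0.1) matches the
distance between cells of clones one event apart. A cut rule based on merge
heights — including the natural "largest relative gap" rule — therefore
recovers only the coarse structure (wild-type vs. tumor, dominant vs.
ancestors) and systematically under-resolves intermediate clones. The
package instead treats the tree as a seeding device and polishes the
partition under the explicit call-error model:

1. cut the tree into `2 * max_k` clusters;
2. iteratively reassign every cell to the consensus genotype maximising its
   likelihood with false-present rate α and false-absent rate β (missing
   calls contribute nothing);
3. propose splitting each cluster on any event called present in an
   intermediate fraction (10–90%) of its members — the signature of two
   clones sharing a cluster — keeping a split only if both halves survive
   the distinctness test below;
4. merge clusters that coincidental call errors could explain.

The distinctness test asks, for a cluster A and an alternative B: could the
cells of A be B-cells with unlucky calls? A member *supports* the
distinction when it exhibits at least 80% of the events distinguishing the
two consensus genotypes (absent where A lacks an event of B, present where
A carries an extra one). The number of supporting cells expected by chance
is Poisson with mean `(n_A + n_B) · P(pattern | α, β)`, multiplied by a
look-elsewhere factor `choose(E, d)` because the d distinguishing events
were themselves selected from the E panel events by the clustering. A
cluster whose observed support has tail probability above `p_merge = 0.05`
is merged into the cluster that best explains it. Two consequences are
worth knowing:

* genuinely rare clones survive — a single wild-type cell among mutated
  clones, or a single early-ancestor cell, is kept, because its pattern
  would need several simultaneous false-present calls (rate α per event)
  to arise by chance;
* a one-to-three-cell cluster that differs from a large clone by one or two
  *absences* is absorbed, because drop-out produces such patterns routinely.
  A true clone of that size and distinctness is statistically
  indistinguishable from noise at these error rates; this is a limitation
  of the data, not of the implementation, and the package resolves the
  ambiguity in favour of fewer clones.

Consensus genotypes use a strict majority of non-missing calls per event;
an exact tie (or all-missing) is *ambiguous* and excluded from downstream
set comparisons. Clusters are labelled by decreasing consensus mutation
count, so `C1` is always the most-mutated (dominant) clone, and a cluster
with an empty present-set is flagged wild-type. If every cell collapses
into one cluster the function returns it with a warning rather than
fabricating structure. All tie-breaks (cell order, cluster labels, merge
candidates) are lexicographic, and cells are sorted by id on entry, so the
result is invariant to input order.

## Order of acquisition

Events acquired together (or so close in time that no sampled cell
separates them) cannot be ordered; they are first merged into event groups.
Raw per-cell presence patterns are too noisy for this at realistic ADO —
within-block pattern similarity (~0.9) matches between-block similarity —
so the pipeline computes patterns over *clone consensus genotypes* (one row
per clone), which the majority vote has denoised: co-acquired events then
match exactly and events separated by any clone differ. Raw-pattern
grouping remains available (and is exact on near-noiseless data) for use
without a prior clustering.

A candidate order π = G1…Gm implies nested genotype states
S0 = ∅ ⊂ S1 ⊂ … ⊂ Sm. Each cell is a noisy observation of one state:

    L(cell | S_k) = Π over non-missing events e of
                    (1-β)  if e ∈ S_k and called present
                    β      if e ∈ S_k and called absent
                    α      if e ∉ S_k and called present
                    (1-α)  if e ∉ S_k and called absent

and the cell's contribution to the order's log-score is
`log( (1/(m+1)) Σ_k L(cell | S_k) )` — a marginal over states with a
uniform prior, not a max-attachment, which keeps the score a proper
log-likelihood and makes an all-missing cell contribute exactly zero. The
defaults α = 0.01 and β = 0.15 mirror the call-error anchors above, with β
inflated beyond the genotype-level 7% to absorb residual within-clone
heterogeneity. Cells of every compartment are included by default.

All m! orders are scored when m ≤ 8 (the presets have 3–4 groups, i.e. at
most 24 permutations); beyond that a deterministic beam search over order
prefixes (width 500, partial orders scored with the prefix states plus one
terminal full state) stands in, and the report is flagged approximate.
Ranking breaks ties lexicographically on the group-id sequence.

Two post-processing summaries interpret the ranked list:

* **Stepwise consensus.** Adjacent groups in the rank-1 order whose
  relative order has support below 60% are collapsed into one step,
  annotated as closely related in time. Support is the
  *likelihood-weighted* fraction of ranked orders agreeing with the pair's
  order — weighting is essential because for small m the ranked list
  contains every permutation, so an unweighted fraction would hover near
  one half even for decisively ordered pairs.
* **Progenitor sensitivity.** The entire inference (clustering, grouping,
  ranking) is re-run without the CD34+CD38− multipotent progenitor cells
  and the two rank-1 orders are compared at the event level. Removing
  cells can remove the only carriers of an intermediate state, in which
  case adjacent groups merge and the order loses *resolution* without
  being contradicted; the comparison therefore reports `identical` (same
  groups, same sequence), `consistent` (no event pair ordered opposite
  ways — the hierarchy is unchanged up to resolution), and the Kendall
  rank correlation over event pairs that both runs resolve. `consistent`
  is the robustness statement of interest.

What the score deliberately does not model: per-event error rates,
back-mutation, copy-number-driven depth changes, doublets, and full
partial-order (branching) enumeration — branches surface post hoc through
the consensus-merge rule and through clones flagged as branching in the
nesting report.

## The synthetic-data generator

`simulate_cells()` draws, per cell, a clone (multinomial in the model
frequencies), and per locus: amplification failure with probability
`ldo_prob` (total depth 0–3 reads), otherwise a negative-binomial depth
(`mean_depth`, size `depth_dispersion`); at heterozygous sites an allele
fraction centred at 0.5 (Beta(20, 20)) that collapses to 0 or 1 with
probability `ado_prob`; and at unmutated somatic loci an alternate-read
leak with probability `fp_prob` at a low Beta(2, 10) fraction, so that
roughly half of leaks pass the presence thresholds. Germline SNPs are
heterozygous in every cell before noise. Defaults: depth 40 (size 10), LDO
0.05, ADO 0.10, FP 0.01. Everything is reproducible from a single integer
seed, and `write_fixture()` emits byte-identical files under a fixed seed.

The four patient presets encode published T-ALL clone architectures — clone
frequencies, diagnostic cell counts (187, 115, 251, 96), 24 somatic events
per patient partitioned into acquisition groups, 32 germline SNPs — with
per-clone genotypes reconstructed from the textual cluster descriptions
(the underlying per-clone event tables were not published; events carry the
published gene labels where given and synthetic `VARxx` labels otherwise).
Points where the reconstruction required a decision:

* X09's 7% intermediate carries the 9p21 deletion that the dominant clone's
  description does not mention; it is encoded as a side branch, so the
  preset contains exactly one branching event.
* XB37's 5% cluster "carrying only a few" variants is encoded as the early
  clone bearing the small STAT5B-containing first group, consistent with
  STAT5B being that patient's early driver; its single wild-type cell is a
  clone of frequency 1/115 so that frequencies sum exactly to one.
* Progenitor compartments are simulated on top of the diagnostic cells
  from a per-patient clone mixture: early clones plus wild-type, with a
  share of fully mutated cells for the two patients whose progenitors were
  reported highly mutated (X09, XB41) and predominantly wild-type for the
  other two. The progenitor mixtures are package choices; the published
  account constrains them only qualitatively.

What the generator does **not** emulate: doublets, cross-well
contamination, per-locus amplification biases (all loci share one depth
distribution), CNV-driven depth shifts, and read-level sequencing error.
Passing the recovery tests therefore demonstrates correctness of the
inference under the modelled noise processes, not robustness to every
artifact of real chips; on real data the QC and concordance outputs are the
guard rails.

## Numerical choices and degenerate inputs

* Likelihoods are computed in log space throughout; the per-cell marginal
  uses a max-shifted log-sum-exp.
* The order-score oracle tolerance in the tests is 1e-9 on instances small
  enough for direct summation.
* Depth files may omit (cell, locus) pairs: they load as depth 0/0 —
  amplicon failure is expected — and the fill-in count is reported.
* Zero-cell genotype matrices round-trip; all-missing cells are valid
  (distance 1 to everything, zero contribution to any order score).
* Panel coordinates are 1-based as in VCF; fusions and deletions carry no
  position and are identified by locus id, and the optional VCF export
  writes them as symbolic-ALT records.
* `run_pipeline()` aborts with the failing stage's name and keeps the
  outputs of completed stages.

## Problem sizes in the test suite

The recovery tests simulate the four presets at their published cell
counts (96–251 cells, 56 loci) over 25 seeds each, cluster-parameter
recovery uses 25 replicates of a three-clone design at 120 cells, and the
order-inference checks use 20 random instances of up to 5 events and 10
cells against the summation oracle plus 20 noiseless 54-cell instances for
exhaustive rank-1 recovery. These sizes give the binomial assertions
enough resolution while keeping the full suite under a minute of
simulation work.

## Known limitations

* Clones smaller than ~3 cells that differ from a neighbour by only one or
  two absences are absorbed by design (see the distinctness test above).
* The error model is global (one α, one β for all events and cells);
  per-event rates would require replicate information the targeted design
  does not provide.
* Order inference assumes a single linear backbone per sample; extensive
  branching is summarised, not enumerated.
* The beam-search path for more than 8 event groups is approximate and
  flagged as such; its agreement with exhaustive enumeration is tested only
  at sizes where both run.
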