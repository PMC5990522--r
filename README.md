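# clonetrace

Clonal architecture and mutation-order inference from targeted single-cell
DNA sequencing.

## The problem

Bulk sequencing of a leukemia sample reports, for each somatic variant, one
allele frequency averaged over millions of cells. It cannot tell whether two
subclonal mutations co-occur in the same cells, and it says little about the
order in which the lesions were acquired — especially for chromosomal
rearrangements, whose bulk VAFs are not interpretable. Targeted amplicon
sequencing of single cells solves both problems: a patient-specific panel of
somatic events (SNVs, indels, fusions, deletions) plus a set of shared
heterozygous germline SNPs is amplified from each single-cell genome,
yielding one reference/alternate read-depth pair per cell per locus.

clonetrace implements the downstream analysis of such data, developed around
panels for childhood T-cell acute lymphoblastic leukemia (T-ALL):

1. **Quality control.** Whole-genome amplification of single cells fails
   locally (locus drop-out, LDO) or loses one allele (allelic drop-out,
   ADO). Both are measured per cell on the germline heterozygous SNPs: LDO
   is the fraction of SNPs with fewer than 4 reads; ADO the fraction of
   covered SNPs whose minor-allele fraction falls below 0.10. Cells with a
   third or more of SNPs affected by the combined (union) rate are
   discarded (`filter_cells()`). Pooled single-cell VAFs are compared with
   bulk VAFs as an orthogonal check (`vaf_concordance()`).
2. **Genotyping.** Each (cell, somatic event) pair is called *missing* below
   10 reads, *present* with at least 2 alternate reads at VAF >= 0.10, and
   *absent* otherwise (`call_genotypes()`).
3. **Clonal deconvolution.** Cells are clustered on the pairwise-complete
   Jaccard distance between genotype vectors,
   `d(c1, c2) = 1 - |P1 ∩ P2| / |P1 ∪ P2|` over events observed in both
   cells, with average-linkage hierarchical clustering. Because drop-out
   flips calls at rates comparable to the difference between nested
   subclones, the dendrogram is over-cut and polished under an explicit
   error model (false-present rate α, false-absent rate β): cells are
   reassigned to the maximum-likelihood consensus genotype, clusters are
   split on events with intermediate presence fractions, and clusters whose
   distinguishing pattern coincidental errors could produce are merged
   (`cluster_cells()`). The result is a set of clones with consensus
   genotypes and frequencies, plus a nesting report of their subset
   relations (`nesting_report()`).
4. **Order of acquisition.** Events with indistinguishable presence
   patterns are grouped (`group_events()`); a candidate order π = G1…Gm of
   the groups implies nested genotype states S0 ⊂ S1 ⊂ … ⊂ Sm. Each cell is
   modelled as a noisy observation of one state with a uniform prior:

       L(cell) = (1/(m+1)) Σ_k Π_events f(call | event ∈ S_k)

   with f = 1−β / β for present/absent calls of in-state events and
   α / 1−α for out-of-state events; missing calls are uninformative. The
   log-score of an order sums log L over cells; all m! orders are
   enumerated (beam search beyond 8 groups) and the ranked list, a
   stepwise consensus (weakly ordered adjacent groups merge into one
   step), and the sensitivity to removing CD34+CD38− multipotent
   progenitor cells are reported (`enumerate_and_rank()`,
   `consensus_order()`, `compartment_sensitivity()`).
5. **Synthetic data with known truth.** `simulate_cells()` generates
   allele-depth matrices from a clone model (acquisition groups, clone
   genotypes and frequencies, 32 germline SNPs) under negative-binomial
   depths with LDO, ADO and false-positive read leakage.
   `patient_preset()` encodes the published clone architectures of four
   T-ALL patients (X09, XB37, XB41, XB47) so that every pipeline stage can
   be validated against ground truth.

## Worked example

Simulate patient X09 (187 diagnostic cells, five clones, plus 20 multipotent
progenitor cells), run QC, cluster, and infer the order of acquisition:

```r
library(clonetrace)

ps  <- patient_preset("X09")
sim <- simulate_cells(ps$model, noise_config(seed = 2), ps$n_cells,
                      n_progenitors = ps$n_progenitors)
flt <- filter_cells(sim$matrix)
flt$qc
#> Cell QC: 207 cells, 32 germline SNPs; 206 passed (99.5%)
#>   median LDO 0.031, ADO 0.097, combined 0.156

g      <- call_genotypes(flt$matrix)
clones <- cluster_cells(g)
clones
#> Clone set: 5 clusters over 206 cells
#>   C1: 119 cells (57.8%), 22 events
#>   C2: 18 cells (8.7%), 16 events
#>   C3: 50 cells (24.3%), 14 events
#>   C4: 14 cells (6.8%), 4 events
#>   C5 [wild-type]: 5 cells (2.4%), 0 events

groups <- group_events(g, clusters = clones)
report <- enumerate_and_rank(g, groups)
report
#> Order report: 4 group(s), 24 ranked order(s)
#>   #1  -1329.093  G3 > G1 > G4 > G2
#>   #2  -1535.680  G1 > G3 > G4 > G2
#>   ...
```

The five clusters recover the simulated architecture: the dominant clone
with 22 events (57.8% here includes the progenitor cells; on diagnostic
cells alone it averages 66% over seeds), the two intermediates (14 and 16
events — the smaller carrying the extra 9p21 deletion), the small
MED12-bearing early clone, and a wild-type population. The rank-1 order
places the MED12 group (G3) first, then the TCF7-SPI1/NRAS group (G1), the
late NOTCH1 group (G4), and the 9p21 deletion branch (G2); the margin to
the runner-up is about 207 log-units. `consensus_order(report)` renders the
steps, and

```r
compartment_sensitivity(g)
#> $identical [1] TRUE   $consistent [1] TRUE   $kendall_tau [1] 1
```

confirms the hierarchy does not depend on the progenitor compartment.

`run_pipeline(run_config(preset = "X09", seed = 2), "out/")` performs the
same stages end to end and writes per-stage TSV outputs, a summary and a
log.

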