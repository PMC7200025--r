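---
title: "Quantifying signal flow through a two-component cascade by regulon overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying signal flow through a two-component cascade by regulon overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Alphaproteobacterial cell-cycle progression is driven by a phosphorelay that
converges on the master transcription factor CtrA: sensor histidine kinases
(DivJ, PleC) control the single-domain response regulator DivK, which acts
through DivL on the essential CckA–ChpT relay that phosphorylates CtrA.
Perturbing any component and profiling expression yields that component's
*regulon* — the set of genes whose transcription responds. If signaling were
a tight pipe, each regulon would coincide (restricted to CtrA targets) with
the regulon of the next component downstream. In practice the pipeline is
leaky: upstream regulons cover only a fraction of the CtrA targets, and the
shortfall at each node measures input from factors that are not in the
modeled pathway.

`regulonflow` implements this analysis as a reusable pipeline: regulon
calling from perturbation RNA-seq tables, intersection with ChIP-derived
binding to define the direct regulon, and a set-algebra quantification of
signal flow over the pathway DAG, together with a synthetic cascade
generator that makes every stage testable without access to raw data.

## Regulon calling

For a paired contrast (mutant vs. wild type, replicate $i$ paired with
replicate $i$), each gene's per-pair log-ratio is

$$d_i = \log_2(\mathrm{RPKM}^{mut}_i + c) - \log_2(\mathrm{RPKM}^{wt}_i + c),$$

with pseudocount $c = 1$ by default. The reported fold change is
$\overline{d}$, and significance comes from the two-sided paired t-test on
the $d_i$. Three filters define the regulon:

| filter      | rule                              | depletion | deletion |
|-------------|-----------------------------------|-----------|----------|
| abundance   | max RPKM across contrast $> r$    | $r = 25$  | $r = 25$ |
| fold change | $|\overline{d}| \ge f$ (inclusive)| $f = 1.3$ | $f = 0.5$|
| significance| $p \le \alpha$ (inclusive)        | $\alpha = 0.05$ | $\alpha = 0.25$ |

Depletion contrasts (conditional shutoff of an essential gene — CckA, ChpT)
produce strong responses and use the strict thresholds; deletion contrasts
(knockout of a dispensable gene — DivJ, PleC, DivK) produce weak responses
and use the relaxed ones. For depletion contrasts, genes sharing an operon
with a regulated gene are counted as regulon members (provenance
`"operon"`); this augmentation is a closure, so applying it twice changes
nothing.

Several conventions here were genuinely open and are fixed as follows:

* *Significance direction.* A regulon member must be significantly
  regulated, so the p-value threshold is an upper bound ($p \le \alpha$).
* *Abundance aggregation.* The abundance filter uses the **maximum** RPKM
  across the contrast's samples, strictly greater than the cutoff: a gene
  fully silenced in the mutant must not be discarded for being low in one
  condition.
* *Tie rules.* Fold-change and p thresholds are inclusive; the abundance
  threshold is strict. These are recorded in the run log.
* *Degenerate t-tests.* With all $d_i$ equal the statistic diverges: all
  zero gives $p = 1$, all equal and non-zero gives $p = 0$ (the limit
  behaviour). With the study's two-replicate design the test has one degree
  of freedom, which is supported, not rejected.
* *Transform.* The test operates on $\log_2(\mathrm{RPKM}+1)$, matching the
  fold-change statistic and tolerating zeros.
* A stricter fold-change cutoff of 2 appears in some displays of the
  original analysis; it is available by constructing a
  `threshold_policy(min_abs_log2fc = 2)` but is deliberately not a default.

## Binding sites and the direct regulon

ChIP peaks are retained when fold enrichment is strictly above 2 and the
FDR q-value is at most 0.05. Assignment to genes is decided by the **peak
summit** (peaks can be wide; the summit is what peak callers localize):

* summit inside a gene (closed 1-based interval): `in_gene` evidence;
* summit in an intergenic interval: `upstream` evidence for each flanking
  gene whose promoter faces the interval — a `+` gene to the right, a `-`
  gene to the left. Between divergent genes both qualify; between
  convergent genes neither does.
* every co-operonic gene of a gene with direct evidence receives `operon`
  evidence.

The "immediate upstream region" has no published width, so by default the
whole intergenic interval counts, with an optional `upstream_cap` (bases
from summit to gene boundary) for stricter analyses. An interval-overlap
mode was considered and rejected as a default because wide peaks would
double-count genes.

The **direct regulon** is the intersection of the total regulon (the union
of the depletion-contrast regulons) with the bound gene set; provenance
records whether each member is bound directly or through an operon partner.
Internally, peaks use 0-based half-open coordinates (BED) and genes 1-based
inclusive (GFF3); all conversion happens in the readers and writers, so no
analysis code does arithmetic on mixed conventions.

Motif scanning (`scan_motif`) matches two exact half-sites separated by a
fixed-length spacer — the CtrA family consensus TTAA-N7-TTAAC is the
built-in default — on both strands, reporting minus-strand hits in forward
coordinates. An `N` in the sequence never satisfies a half-site position
but is accepted in the spacer.

## Flow quantification

Let $D$ be the member set of the direct regulon, normalized to 100%, and
$R_X$ the regulon used for node $X$. Then

* node input: $\mathrm{input}(X) = 100\,|R_X \cap D| / |D|$,
* edge flux: $\mathrm{flux}(X{\to}Y) = 100\,|R_X \cap R_Y \cap D| / |D|$,
* missing input:
  $\mathrm{missing}(Y) = 100\,\bigl|(R_Y \cap D) \setminus
  \bigcup_{X \in \mathrm{pred}(Y)} R_X\bigr| / |D|$,

with missing input undefined at source nodes. Every quantity is a multiple
of $100/|D|$ and the gene lists behind every number are retained. Because
regulons overlap, $\mathrm{missing}(Y) + \sum_X \mathrm{flux}(X{\to}Y)$ can
exceed $\mathrm{input}(Y)$; equality holds exactly when the predecessors'
contributions are disjoint on $D$. Summaries round to integers; stored
values keep full precision.

Two modeling choices deserve emphasis:

* *Flux regulons.* Deletion mutants respond weakly, so for the flow
  analysis their regulons are recomputed without the p filter (fold change
  and abundance only); depletion nodes keep the full operon-augmented
  policy. Every flux regulon contains its strict counterpart.
* *Unmeasured nodes.* DivL and postulated intermediate regulators have no
  measurable regulon. Their set is defined as (union of nearest measured
  ancestors) ∩ (union of nearest measured descendants), where "nearest"
  skips over other unmeasured nodes. This is an interpretation — it
  reproduces "receives input from its upstream kinases" without inventing
  data — and it is resolved transitively, so chains of unmeasured nodes are
  well-defined.
* *Overlap denominators.* `overlap_fraction` defaults to the first
  (subject) regulon as denominator — "the overlap of the DivK regulon with
  DivJ" divides by DivK — with `second` and `union` available.

`infer_hidden_inputs` turns any node whose missing input exceeds a
threshold (default: any at all) into an explicit hidden node
`missing_<node>` feeding that node, which the DOT export draws as a dashed
oval, line thickness proportional to flux.

## The synthetic cascade generator

`simulate_cascade` is the package's test bed. It emulates the study design:
a single-contig genome (900 bp genes, 300 bp gaps, alternating strands —
chosen so peak assignment can be hand-checked), a planted direct-regulon
universe $D$ (default 94 genes of 3,000), two biological replicates,
deletion and depletion contrasts, ChIP peaks upstream of every $D$ gene
plus decoys, and operons over runs of adjacent genes.

Signal propagates from the DAG's sources: sources carry all of $D$; a gene
carried by $X$ crosses the edge $X{\to}Y$ independently with the edge's
transmission probability; non-source nodes may additionally receive
exogenous genes (drawn from the part of $D$ their predecessors did not
deliver, so that the planted fraction is genuinely unexplained input). A
node's true regulon is the subset of its genes that reaches the sink, which
is exactly what a perturbation of that node can propagate to CtrA-level
expression. Perturbation shifts affected genes by a signed per-gene effect
(direction coherent across contrasts); replicate RPKMs are log-normal
around condition means.

Default parameters, chosen once as the study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 3000 | few-thousand-gene alphaproteobacterial genome |
| `direct_regulon_size` | 94 | ~90-gene direct regulon |
| `n_replicates` | 2 | the study's paired design |
| `replicate_noise_sd` | 0.15 (log2) | ~11% CV; the 1-df paired test only has power when replicate noise is well below effects, as the study's hundreds of significant genes imply |
| `effect_log2_mean`, `effect_log2_sd` | 3, 0.5 | depletion responses well above the 1.3 threshold |
| `deletion_effect_scale` | 0.5 | weak knockout responses, still above the 0.5 threshold |
| `baseline_log_rpkm_mean/sd` | 8, 1.5 | median ~256 RPKM; $D$ genes floored at 4× the abundance cutoff so the planted signal is assayable |
| `decoy_peak_count` | 100 | half fail the peak filters, exercising them |

The generator is seed-deterministic (integer-seeded base R RNG, no hash
ordering) down to byte-identical output files.

What the simulation does *not* emulate: read-level count noise (negative
binomial dispersion), condition-dependent library effects, peak-width
variation, overlapping genes, multi-contig genomes, and regulatory
amplitude (all effects are presence/absence at the set level, mirroring the
method's own blindness to amplitude). Passing recovery tests therefore
demonstrates the correctness of the set algebra and threshold logic under
the stated noise model, not robustness to every artifact of real RNA-seq.

## Protein-stability fitting

Translation-shutoff immunoblot series are OD-normalized; because the
culture keeps growing after shutoff, per-biomass signal underestimates
total protein. `correct_for_dilution` multiplies by the growth factor
$\mathrm{OD}(t)/\mathrm{OD}(0)$ — the unique correction making a stable
protein constant — and clears the growth column so it cannot be applied
twice. `fit_half_life` fits $A e^{-kt}$, by log-linear regression by
default (standard for blot quantifications; the direct nonlinear fit via
Levenberg–Marquardt is available and agrees within 1% on clean data).
Rates below $10^{-12}\,\mathrm{min}^{-1}$ report an infinite half-life; a
negative fitted rate is clamped to zero with a warning rather than an
error, since rising signal is a real artifact of blot quantification.
`percent_remaining` evaluates the growth-corrected fraction at an observed
timepoint (interpolation only on request, flagged), averaging across
replicate series when several are given.

## Problem sizes and numerical tolerances

The test suite checks exact closed forms at tolerance $10^{-9}$, p-values
against `stats::t.test` at $10^{-10}$, flow percentages against per-gene
enumeration exactly, and parameter recovery on cascades of 500
direct-regulon genes in 2,000-gene genomes across 20 seeds (binomial
three-sigma bounds), with one full 5,000-gene pipeline run. These sizes
were chosen to make sampling error bounds meaningful while keeping the
suite fast on a laptop.

## Known limitations

* The flow algebra counts genes; it deliberately ignores the amplitude of
  transcriptional changes, so a weakly and a strongly transmitted gene
  count equally.
* Regulon content depends on the thresholds; the flux-regulon policy
  (dropping the p filter for deletion nodes) trades false positives for
  sensitivity and is the right trade only because downstream quantities
  intersect with $D$.
* Upstream assignment without a cap can attribute a summit to a promoter
  hundreds of bases away; use `upstream_cap` when the genome is compact.
* The unmeasured-node algebra bounds, but cannot measure, flux through
  nodes like DivL; percentages at and around such nodes inherit that
  uncertainty.
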