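---
title: "Methods: propagating non-coding variant effects through signalling and regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propagating non-coding variant effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, its numerical
choices, and the design decisions taken where the method left room for
interpretation. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute.

## The two-layer propagation model

The unit of analysis is one patient's set of *SNP-affected* proteins: genes
whose regulatory elements are predicted to gain or lose a binding site
because of a variant that patient carries. These seeds perturb the cell
through two qualitatively different layers, modelled separately:

1. **Signalling layer (global diffusion).** Protein-protein signalling is
   modelled as a directed graph; a perturbed protein influences everything
   downstream of it, with influence decaying along paths. We use the
   closed-form diffusion kernel

   $$K = (1-\alpha)\,(I - \alpha A_w)^{-1},$$

   where $A_w$ is the out-degree-weighted adjacency matrix
   ($A_w[i,j] = 1/\mathrm{outdeg}(i)$ for each edge $i \to j$) and the
   retain parameter $\alpha$ is the fraction of heat a node passes onward
   per step. $K$ is the steady state of a random walk with restart: row $i$
   is the equilibrium distribution of one heat unit injected at node $i$.
   The patient's heat vector is $H_\text{out} = h\,K$ with $h$ the 0/1
   indicator row vector of the seeds — one unit per distinct SNP-affected
   protein, so a patient with more affected proteins injects more total
   heat, while a protein hit by several SNPs still injects exactly one unit
   (SNP multiplicity is kept in the provenance table, not in the heat).

2. **Regulatory layer (one-step push).** TF-target interactions are
   shallower and more promiscuous than signalling cascades, so heat reaching
   a transcription factor is propagated exactly one step: a heated TF with
   $\#TG$ targets sends $H_{TF}/\#TG$ to each of them, and a target gene
   averages the incoming contributions over the number of its heated
   regulators. Global diffusion over the regulon graph would let
   pleiotropic TFs dominate; the one-step push reflects a single round of
   transcriptional response.

### The retain parameter

$\alpha$ is set from the edge count $E$ of the propagation substrate by the
log-linear heuristic $\alpha = m \log_{10} E + b$ with the published
calibration $m = -0.02935302$, $b = 0.74842057$ (denser networks diffuse
further per step, so less retention is needed). The heuristic is unbounded,
so the result is clamped to $[0.01, 0.99]$ — the upper bound guarantees
$(I - \alpha A_w)$ is invertible for sub-stochastic $A_w$, the lower bound
keeps the diffusion non-trivial. Both constants and an explicit $\alpha$
override are exposed in `pipeline_params()`.

### Dangling nodes and conservation

The method's reference implementation is silent about sink nodes
(out-degree 0). Our default, `dangling = "self_loop"`, gives each sink a
self-edge of weight 1, which makes every row of $A_w$ — and hence of $K$ —
sum to one, so **total heat equals the seed count exactly**. This
conservation is load-bearing: it makes heats comparable across patients with
equal seed counts and gives the null model a closed-form mean. The
alternative `dangling = "zero_row"` (heat leaks at sinks) is kept for
sensitivity analysis only.

### Orientation

Heat flows along edge direction: rows of $A_w$ are sources, and $H$
multiplies $K$ from the left. A kinase therefore heats its substrates, not
vice versa.

## The random-seed null and the Z filter

Raw heat is confounded by topology: hubs and well-studied proteins collect
heat from almost any seed set. For each patient we therefore draw the same
number of seeds at random, push each replicate through both layers, and
summarise per node the null mean and SD over $R$ replicates
($R = 10{,}000$ in the published protocol; the desk-scale test conditions
use $R = 1{,}000$). A node is retained when

$$Z = \frac{H_\text{real} - \overline{H_\text{random}}}{\mathrm{SD}\,H_\text{random}} > 2$$

strictly. Choices worth stating:

* **Upper tail only.** Only excess heat is evidence of perturbation, so the
  test is one-sided; a node can never be "significantly cold".
* **SD = 0 degenerate rule.** If the null never varies, the node is
  significant iff its real heat exceeds the null mean ($Z$ reported as
  $\pm\infty$ or 0).
* **Population SD** (divide by $R$): at $R = 10^3$–$10^4$ the distinction
  from the sample SD is negligible; the population form matches the
  plain reading of the formula.
* **Linearity fast path.** Because propagation is linear in the seed
  indicator, a replicate's heat is just the sum of the corresponding kernel
  rows, and all $R$ replicates are one sparse-times-dense matrix product.
  The tests verify this equals naive per-replicate propagation *exactly*,
  and that uniform-null means match the closed form
  $(n_\text{seeds}/N)\cdot\text{colsums}(K)$ at $R = 10{,}000$.
* **Ensemble reuse.** A null depends only on (kernel, regulons, seed count,
  mode, $R$, RNG seed), so patients with equal seed counts share a cached
  ensemble. Degree-matched ensembles depend on the actual seeds and are
  never cached across patients.
* **Degree-matched mode.** Each real seed is replaced by a random node of
  comparable out-degree (exact degree when at least 20 nodes share it,
  otherwise a log2-spaced bin, widened if empty), without replacement within
  a replicate. This is the hub-bias sensitivity variant.
* **Eligible nodes.** Null seeds are drawn from the giant-component node
  set — the propagation substrate itself.
* **Seeding the regulatory layer.** All heated TFs feed the one-step push;
  significance is applied afterwards, per layer. Restricting the push to
  Z-significant TFs is possible in principle but would make the regulatory
  null conditional on the signalling filter; we keep the layers' nulls
  parallel (the same replicate heats feed both layers).

### The two readings of the target-gene formula

The printed form of the one-step push divides by the TF's target count
twice, while the accompanying text defines the second denominator as the
number of TFs regulating the target. We implement the **text reading** as
the default:

$$H(TG) = \frac{\sum_{TF:\,H_{TF}>0} H_{TF}/\#TG_{TF}}{\#TF_{TG}},$$

because it has a clean interpretation (average over the regulators that
actually carry signal) and keeps $H(TG)$ on the scale of the contributing
heats. The literal printed variant
($\sum_{TF} H_{TF}/\#TG_{TF}^2$) is available as
`variant = "printed"` everywhere the push appears, including the null, so
the choice can be audited.

## Variant annotation

* **Promoters** span 5 kb upstream of the TSS through the end of the first
  exon, strand-aware, clipped at the chromosome boundary. Gene models whose
  first-exon end lies on the wrong side of the TSS are rejected loudly.
* **Coordinates.** Internally everything is 1-based closed (the native
  convention of R/Bioconductor interval tools); BED input (0-based
  half-open) and VCF input (1-based) are converted at the readers and
  nowhere else, so a single convention holds throughout and off-by-one
  drift cannot accumulate.
* **TFBS presence** is defined relative to the motif itself: the best
  log-odds score over all motif-length windows containing the variant, on
  both strands, must reach `score_fraction` (default 0.8) of the motif's
  maximum achievable score. A relative threshold is invariant to motif
  length and information content, which an absolute cutoff is not; the
  source tools' thresholds are not printed, so the default is surfaced in
  the configuration rather than buried. A call is a *loss* when only the
  reference allele carries a site and a *gain* when only the alternate
  does; "no change" is never a call.
* **PFM scoring constants.** Position frequency matrices get a pseudocount
  of 0.5 per cell and a uniform background of 0.25 before log-odds
  conversion (both configurable), so no entry is $-\infty$ and a single
  mismatch is penalised but not fatal for informative motifs.
* **Indels** are accepted: the alternate window is rebuilt around the
  substituted sequence and all windows overlapping it are scanned.
* **miRNA sites** use exact seed matching: the site is present iff the
  reverse complement of miRNA nucleotides 2–8 occurs in the site sequence.
  Hybridisation-energy models add little for a gain/loss decision at a
  known site and are out of scope.
* **Epigenetic filter.** TFBS calls survive only when the called site
  interval overlaps at least one ChIP-seq peak from the union of supplied
  peak sets; miRNA calls pass through (they are not TF-binding events). We
  require overlap with *any* peak, not a peak of the disrupted TF itself —
  requiring TF-matched peaks is stricter than the evidence usually
  supports. An empty peak union drops every TFBS call with a loud warning
  rather than silently passing everything.
* **Genotype handling.** Any genotype with at least one alternate allele
  counts as carrying the variant; dosage effects on TF binding are too
  poorly quantified to model, so het and hom-alt collapse. Patients with no
  carried variants stay in the cohort and yield empty results.
* **Identifiers** are opaque strings; mapping between protein and gene
  namespaces is input preparation, not the package's job.

## Patient results and cohort aggregation

A patient's signalling subnetwork is the **induced subgraph** on
(significant nodes ∪ seeds): the method defines which nodes survive but not
which edges, and the induced rule is the simplest choice that adds no
modelling assumptions. Seeds are always retained (flagged `is_seed`) even
when their own Z ≤ 2 — they are the injection points. Significant
regulatory edges connect retained, heated TFs to targets with Z above the
threshold.

Cohort aggregation counts, per node and per TF→target edge, the patients in
whose significant networks it appears; "commonly perturbed" means strictly
more than the threshold (default 100 patients, matching the full-cohort
protocol; a fraction of the cohort can be given instead, which is what the
desk-scale tests use). Cross-disease comparison unions two cohort summaries
and labels features shared/specific, carrying the per-cohort counts
unchanged. Per-disease networks are the union over patients of significant
features; propagating the pooled seed set in a single run is available as
`cohort_mode = "pooled"` since the aggregation rule is not uniquely
determined by the method description.

## Stratification

The binary patients × TF→target-edge matrix is the clustering input.

* **Jaccard distances** between patient rows; two all-zero patients are at
  distance 0 by convention (logged), since indistinguishable patients
  should co-cluster rather than be undefined.
* **PCA on the similarity matrix** $S = 1 - D$, column-centred. Whether the
  source protocol decomposed similarities or distances, centred or not, is
  not stated; similarity + centring makes the leading component align with
  the dominant co-perturbation pattern. The embedding keeps
  `use_components = 3` components, or more if needed to reach 95%
  cumulative explained variance. Component signs are fixed by forcing each
  component's largest-magnitude loading positive, making repeated runs
  byte-identical.
* **k-means with silhouette-selected k** (ties toward the smaller k), 10
  restarts under a fixed RNG seed; the inertia (elbow) curve is always
  reported alongside because the selection is acknowledged to carry
  subjectivity, and `--k` overrides it.
* **Cluster representatives**: an edge represents a cluster when present in
  at least `min_fraction = 0.5` of its patients — a majority rule; the
  exact fraction used in the source figures is not printed, so it is
  configurable.
* **Girvan–Newman modularisation** ignores edge direction (as the
  GLay-style implementations do), collapses duplicate undirected edges and
  self-loops, removes the highest-betweenness edge repeatedly (recomputing
  betweenness each time, ties broken by lexicographic edge label so the
  procedure is deterministic), and returns the partition of highest Newman
  modularity along the removal sequence. An edgeless graph modularises to
  singletons with modularity 0.
* **Overrepresentation** is a one-sided hypergeometric upper-tail test per
  annotation set with Benjamini–Hochberg adjustment across the tested sets;
  the universe is the propagation substrate (signalling nodes) or the
  regulon gene space, supplied explicitly.

## The synthetic study conditions

`gen_fixture()` generates every input from a seeded RNG; the same
(spec, seed) pair reproduces byte-identical fixtures, and a generation-time
self-check re-runs the annotation modules and aborts unless the emitted
calls equal the designed ones.

The default conditions — used by the test suite and `scripts/acceptance.R`
— are a 500-node directed network with roughly 2,000 edges, 40 TFs, 60
patients in 3 planted clusters, and 1,000 null replicates per ensemble
(10,000 remains the recommended analysis setting; 1,000 keeps the full
cohort run within seconds at this scale without changing any conclusion of
the tests).

What the generator emulates, and how:

* **Heavy-tailed out-degrees** in the background graph (a Zipf-like degree
  law), so the null model's hub behaviour is actually exercised.
* **Planted cascades**: each cluster has a seed panel wired through relay
  nodes into designated TFs (two directed hops, verified ≤ 4 at
  generation), with *no incoming edges from the background graph*, so the
  designed downstream set receives heat only from its own panel and
  recovery is an analytic property of the method rather than a lottery.
  The designated TFs carry cluster-specific regulon signatures.
* **Continuous within-cluster heterogeneity**: every non-panel designed
  variant (noise genes, miRNA hosts) is carried independently at rate 0.2,
  and each noise gene feeds a dedicated small-regulon TF. Cohort rows thus
  differ smoothly within a cluster, as real patients do. This matters for
  model selection: if within-cluster rows were identical atoms, silhouette
  would degenerately favour splitting duplicate groups — a property of the
  silhouette statistic, not of the stratification under test.
* **Analytically certain binding calls**: motifs are consensus PFMs
  (counts 10/0, pseudocount 0.5), for which a single mismatch scores below
  0.8 of the maximum — so presence means an exact consensus match, and a
  planted variant provably creates or destroys exactly one site. A
  rejection loop re-rolls the local sequence on the (rare) spurious match
  with another motif. Designs include peak-filter negative controls
  (valid TFBS change outside every peak) and strict promoter-boundary
  cases (a variant on the first promoter base, and one a single base
  outside).
* **What it does not emulate**: linkage disequilibrium, realistic allele
  frequencies, genotyping ascertainment, multi-chromosome genomes,
  overlapping regulatory elements, or biological correlation between
  signalling and regulon layers beyond the planted structure. Passing
  tests therefore demonstrate correctness of the machinery and
  recoverability of planted structure under realistic noise — not
  biological validity on any real cohort.

## Numerical choices, briefly

* Exact dense solve for $K$ (the kernel is closed-form; no iterative
  truncation error), verified against the geometric power series to 1e-8.
* $\alpha$ clamp $[0.01, 0.99]$; row sums of $K$ checked to 1e-9.
* Heat conservation asserted to 1e-9; seed-set linearity exact.
* k-means: 10 restarts, fixed seed; silhouette on Euclidean distances in
  the retained embedding.
* Girvan–Newman tie-break: lexicographic on the sorted endpoint pair.
* Jaccard NaN (two empty rows) → 0, logged.
* All RNG consumption goes through a seed argument and restores the
  caller's RNG state.

## Known limitations

* The regulatory push is one-step by design; targets of pleiotropic TFs are
  prioritised only through the averaging denominator.
* Edge signs (activation/inhibition) are carried through I/O but ignored by
  propagation, which models influence magnitude, not direction of effect.
* The epigenetic filter is binary peak overlap; chromatin accessibility or
  conformation are not modelled.
* Enhancer-to-gene assignment comes from the annotation input; no
  distance-based guessing is attempted.
* The null randomises seeds, not topology; it controls for hub bias given
  the network, not for errors in the network itself.
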