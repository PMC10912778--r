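---
title: "Methods: protease-controlled gene regulation at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protease-controlled gene regulation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(calpainGRN)
```

This vignette explains the models behind each stage of the pipeline, the
parameters that matter, what the synthetic generator does and does not
emulate, and the numerical choices that were genuinely open.

## The biological model

A transmembrane calpain protease (DEK1 in the moss *Physcomitrium patens*
is the motivating system) cleaves a subset of transcription factors. When
the residue exposed immediately after the cut (P1′) is destabilizing under
the N-end rule, the cleaved TF is degraded by the N-degron pathway (NERD):
the TF protein disappears while its transcript is unaffected. The
observable consequence is *misregulation of the TF's targets* across a
mutant series: targets of a cleaved **activator** are higher in the
protease null (the activator survives) and lower in the overexpressor;
targets of a cleaved **repressor** show the mirror pattern. The pipeline
reconstructs the regulatory network from expression covariation, reads
those signatures per gene, classifies predicted cleavage sites by their
N-terminal fate, and intersects the two lines of evidence.

## Synthetic study conditions

The generator's defaults are the study conditions used by the whole test
suite: five genotypes — wild type (calpain activity $a = 1$), a null
mutant and a loop-deletion line ($a = 0$), a partial deletion ($a = 0.5$)
and an overexpressor ($a = 2$) — sampled at days 3, 5, 9, 12 and 14 with
three replicates; 20 TFs in a three-layer hierarchy over 300 targets, two
parents per downstream node; 30% repressive edges; half of the TFs
cleaved.

Regulator activity on the log2 scale is

$$x_j(s) = L + A_j \sin(2\pi d_s / T_j + \phi_j) + \eta_{js},$$

with level $L = 4$, amplitude $A_j \sim U(0.4, 0.7)$, random period and
phase, and intrinsic fluctuation $\eta \sim N(0, 0.5^2)$. Two choices here
are deliberate and worth explaining:

* **Intrinsic regulator fluctuation propagates downstream.** The real
  network was inferred from a few hundred heterogeneous RNA-seq libraries;
  at desk scale, a design with only five distinct days would make all
  regulator profiles collinear (rank ≤ 5) and parent identity
  unrecoverable *in principle*. The $\eta$ term models biological
  regulator variability that transmits to targets and is what makes
  tree-ensemble inference identifiable here. Measurement noise
  (`noise_sd`, default 0.05) is added independently per gene and does not
  propagate.
* **The activity level sets mutant effect sizes.** A cleaved TF acts with
  protein multiplier $m_j(g) = e^{-\kappa a_g}$ ($\kappa = 1$), so the
  genotype shift of a target scales with $L$ while the residual noise
  scales with $\eta$; $L = 4$ keeps the weakest single-parent contrast
  (WT vs overexpressor) reliably detectable at $q < 0.1$.

A target's log-mean is its baseline plus $\sum_j s_j w_j\, x_j(s)\,
m_j(g)$ over its parents ($s_j \in \{\pm 1\}$, $w_j \sim U(0.8, 1.2)$).
Additive regulation on the log scale is the simplest generative link that
reproduces the sign and ordering structure the downstream analyses use;
Hill-type kinetics would add parameters without changing any consumed
statistic. Two further generator constraints keep the ground truth
unambiguous:

* the cleaved parents of any one target share a single sign, so each
  planted gene is a well-defined activator- or repressor-target (mixed
  cleaved inputs would cancel and make "the" planted profile meaningless);
* parent sets are rejection-sampled so the day-curve correlation between
  any two parents of one node stays below 0.3, which (given the bounded
  weight and amplitude ratios) guarantees that every true edge's
  regulator–target covariation carries the planted sign.

TF transcripts are genotype-invariant by construction — post-translational
control — so cleaved TFs are themselves never "misregulated", and mutant
effects live entirely on cleaved-TF → target edges. The proteome gives
every gene product a random sequence; cleaved TFs receive 2–4 sites with
destabilizing P1′ residues, all other proteins 0–2 sites with stabilizing
ones.

What the generator does **not** emulate: read-level count noise and
mapping artifacts (a negative-binomial option exists but Gaussian-on-log is
the default so the DGE model is exact), transcriptional feedback onto
regulator mRNA, cooperative/nonlinear regulation, unequal library sizes,
and cleavage-site prediction errors (site tables are consumed as given, as
in the real analysis). Passing tests therefore demonstrate correctness of
the machinery and recoverability under the stated model, not robustness to
every artifact of real RNA-seq.

## Network inference

Per gene, a random forest (1000 trees, √p feature subsampling, fully grown
— the GENIE3 convention; the engine is `ranger` with one thread and a
fixed seed for determinism) regresses its profile on all regulator
profiles, excluding the gene itself. Importance is total impurity
reduction, normalized to sum to one per target; constant genes get zeros.
Edge direction is the sign of the Pearson correlation between regulator
and target over the *time-course column set* — wild type plus the
deletion mutants — falling back to the global correlation when the
time-course value is numerically zero (|r| < 1e−12). The overexpressor is
excluded from the sign set deliberately: strong attenuation ($m = e^{-2}$)
suppresses the covariation the sign is read from, and including it leaves
near-zero correlations for targets with multiple cleaved parents whose
sign would be decided by noise. Which column set defines directionality
was an open choice; both correlations are stored on every edge.

Top-k selection keeps the 10 highest-importance inbound edges per target
(ties: higher |time-course r|, then regulator id) — ties are real at small
sample sizes, so the tie-break is part of the contract.

## Subnetworks and hierarchy

Louvain modularity maximization runs on the undirected projection with
summed directed weights (directed modularity variants are out of scope).
Community labels are Roman numerals by decreasing size; label ties are
broken by the lexicographically smallest member so partitions are
invariant to node input order under a fixed seed. Local reaching
centrality uses the N−1 denominator (self excluded); the alternative
"fraction of the total subnetwork" reading is a documented configuration
of the same quantity. The inter-subnetwork analysis tabulates
(source subnetwork, target subnetwork) × sign counts and applies a χ²
test without continuity correction; cells with Pearson residual > 4 are
reported as enriched connections. Cells with expected count < 1 are
flagged but the test is still reported.

## Differential expression

The time-course model is a Gaussian linear model per gene: null = natural
spline of day (df = 3, reduced if fewer distinct days), full = null + a
genotype (or trait) main effect. The reported effect size is the
likelihood ratio $\mathrm{LRT} = n\,\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$;
the signed coefficient $b$ is positive when the gene is higher in the
second genotype of the contrast (this orientation is fixed package-wide
and re-derived from stored contrast metadata when profiles are
classified). p-values use the exact $F(1, n-k)$ reference of the same
comparison rather than the asymptotic $\chi^2_1$: at $n = 30$ samples per
contrast the $\chi^2$ tail is anti-conservative by a factor $\approx
n/(n-k)$ and measurably mis-calibrates the null, while the F reference is
exact under the Gaussian generator. One further subtlety: with only five
distinct days, df = 3 under-fits arbitrary day patterns and the leftover
lack-of-fit inflates both models' residuals, making p-values
conservative; calibration checks therefore use the saturated basis
(df = 4 at five timepoints), while df = 3 remains the default aimed at
denser real time grids. A genotype × time interaction is
omitted by default (the mutant effect in the generative model is a level
shift); it can be added by extending the design, but none of the consumed
statistics need it.

Profile classification gates all three contrasts at $q < 0.1$ (the
relaxed reporting level; $q < 0.01$ is the strict one) and requires the
(+, −, +) pattern on (null vs WT, overexpressor vs WT, null vs
overexpressor) for activator targets, (−, +, −) for repressor targets.
Cumulative misregulation is the plain sum of the three LRT statistics.

## NEAT

For gene sets A (sources) and B (targets), the directed edge count
$n_{obs}$ from A to B is referred to
$\mathrm{Hypergeom}(D, d_B, o_A)$: of the $D$ edges, $d_B$ end in B, and
the $o_A$ edges leaving A are an exchangeable draw from them
($n_{exp} = o_A d_B / D$). Two-sided p doubles the smaller tail (capped
at 1); one-sided is available. In batch mode the focal question is "how
strongly does subnetwork S regulate set G", so the subnetwork block is the
source side and the gene set the target side — this orientation is what
makes sets of (mostly parentless) differentially expressed targets
testable at all. BH adjustment runs across the whole batch, calls at
FDR 0.01. Degenerate margins ($o_A = 0$ or $d_B = 0$) yield p = 1.

## Cleavage classification

The default N-terminal class table encodes the canonical N-end-rule
residue sets — destabilizing (primary, secondary, tertiary:
R K H F W Y L I D E N Q) → NERD; Nt-acetylation substrates
(A S T C G V) → "other"; M P → unchanged — and is user-replaceable, since
the exact regular expressions of any given study are data, not model.
Site frequencies are scaled by protein length; SLC categories are 1-D
k-means (k = 5) on log frequencies with labels ordered by centroid.

The mixture step clusters proteins on centered-and-scaled PCA scores of
**log-transformed** per-class and overall frequencies, Gaussian mixtures
with 1–9 components selected by BIC. An SLC one-hot block was considered
for the feature matrix and rejected: at desk scale the binary dummies
dominate the likelihood, BIC clusters form on the SLC lattice, and the
NERD-signature group is absorbed into a mixed cluster; the log-frequency
features carry the same abundance information continuously. Site-free
proteins produce exactly duplicated rows that make every multi-component
covariance singular, so a seeded jitter (sd 0.01 on PC scores) is added
before fitting — a tie-break, three orders of magnitude below the
between-group separation. A cluster is NERD-like when its mean NERD-site
frequency exceeds the global mean; which clusters a given study labels
NERD-like is ultimately interpretive, and this rule is the stated proxy.

## Target tracing and FDGENEA

Upstream regulons are breadth-first traversals of reversed edges up to
order 3, restricted to regulators, cycle-safe, with the focal gene
excluded; a TF reachable at several orders counts once, at its minimal
order. Control fractions (direct = NERD-like, indirect = misregulated,
either) are computed over the order-3 TF set — TFs only, matching the
"percentage of upstream TFs" reading. The final filter keeps edges with a
NERD-like source and a misregulated target; direct targets are the
retained TFs, indirect targets the retained genes, "both" their
intersection.

FDGENEA encodes traits as genotype-level binary factors expanded to
samples (constant columns are flagged unusable), runs the trait term
through the same LRT engine at $q < 0.01$, performs three NEAT runs per
trait (up, down, combined; the combined run drives the heatmap, the
directional runs the +/− annotations), and isolates weakly connected
components of the subgraph induced on significant genes *plus their direct
upstream regulators* — attaching non-significant regulators can merge
otherwise separate groups, which is accepted as it reflects the actual
regulatory topology. Node statistics use the signed effect
$s = \mathrm{sign}(b)\cdot\mathrm{LRT}$ (0 when not significant); the
`_cb` columns sum $s$ and the `_cab` columns sum $|s|$ over first-order
and total downstream scopes within the component — the signed/absolute
distinction is only meaningful because the summand is signed, which is
why $s$ is not the raw (nonnegative) χ². The label-permutation null is
implemented at the *sample* level: permuting trait labels across
genotypes would leave most permuted traits partially confounded with
calpain activity (any genotype split that separates activity levels
carries real signal), so the genotype linkage must be broken for a
meaningful negative control.

## Pipeline, seeds, problem sizes

`run_pipeline()` executes simulate/load → GRN → structure → DGE/profiles
→ NEAT → cleavage → targets → regulons → FDGENEA, writing TSV tables,
GraphML networks and a manifest (per-stage child seeds, file hashes,
runtimes). One global seed is fanned out to per-stage seeds via a stage-name
hash so any stage can be rerun in isolation. All tabular outputs are TSV;
networks are Cytoscape-compatible GraphML.

Test-suite problem sizes are the package's own desk-scale choices: the
default 20 × 300 configuration for recovery tests, 980-gene null runs for
calibration, 15-node graphs against a 10⁵-draw permutation oracle for
NEAT, 20-node graphs against brute-force reachability for LRC. The
real-data scale (tens of thousands of genes, hundreds of libraries) is
explicitly not a default.

## Known limitations

* The generator's identifiability rests on propagated regulator
  fluctuation; on real data the analogous role is played by condition
  diversity, and inference quality degrades with design collinearity.
* Gaussian DGE is exact for the generator but a stand-in for count-based
  error models on real data; the pipeline consumes only (LRT, q, b), so
  any engine producing those can be substituted.
* NEAT assumes exchangeable edges given degree totals; strong degree
  heterogeneity beyond the conditioned margins is not modeled.
* The NERD-like flag is a cluster-level proxy; per-protein calls inherit
  its granularity.
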