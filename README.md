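# calpainGRN

Dissecting post-translational protease control of gene regulation from
multi-genotype time-course expression data.

## The problem

Calpains are cysteine proteases that gate cell fate transitions. The plant
calpain DEK1 acts post-translationally: it cleaves transcription factors
(TFs), and when the neo-N-terminus exposed by a cut is a destabilizing
residue, the TF is routed to N-degron (N-end rule) degradation. The TF's own
transcript stays unchanged — only its protein disappears — so the protease's
footprint appears one step downstream, in the *targets* of the cleaved TFs.
This package implements the network-based strategy for finding those
footprints in a mutant series (protease null and partial-deletion lines, an
overexpressor, and the wild type) sampled along a developmental time course:

1. **Signed GRN inference** — GENIE3-style tree-ensemble regression ranks
   regulator→target edges by importance; Pearson correlation along the
   WT + deletion-mutant time course gives each edge an activating (+) or
   repressive (−) sign; the top *k* = 10 inbound edges per gene are kept.
2. **Network structure** — Louvain communities ("subnetworks" I, II, …),
   a regulator hierarchy ranked by local reaching centrality
   LRC(v) = |reachable from v| / (N−1), and a χ² analysis of
   inter-subnetwork edges split by sign (Pearson residuals > 4 are called
   enriched connections).
3. **Misregulation profiles** — per-genotype-contrast spline-LRT
   differential expression; genes up in the null mutant, down in the
   overexpressor (and consistent between mutants) are *activator targets*,
   the mirror pattern marks *repressor targets*; the summed χ² statistic of
   the three contrasts is a gene's cumulative misregulation.
4. **NEAT** — network enrichment analysis test: are there more directed
   edges from a subnetwork into a candidate gene set than the
   hypergeometric null expects (n_exp = o_A·d_B/D)?
5. **N-degron classification** — predicted cleavage sites are classified by
   their P1′ residue (NERD / acetylation-route / unchanged), per-protein
   site frequencies are length-scaled, binned into five site-abundance
   categories (1-D k-means), and clustered by PCA + Gaussian-mixture (BIC);
   clusters with above-average NERD frequency are *NERD-like*.
6. **Target tracing** — upstream regulons to third order
   (TF3→TF2→TF1→gene), fractions of directly (NERD-like) and indirectly
   (misregulated) protease-controlled upstream TFs, their correlation with
   cumulative misregulation (Kendall/Pearson), and the final filter: edges
   with a NERD-like TF source and a misregulated target define the direct
   (TF) and indirect (target) protease target sets.
7. **FDGENEA** — factorial differential gene expression network enrichment
   analysis: binary phenotypic traits are tested gene-wise (trait term added
   to the spline-of-day null model), associated genes are mapped to
   subnetworks via NEAT, and trait-associated subgraphs are isolated with
   per-node cumulative signed effect sizes (`*_cb` = Σ sign(b)·LRT,
   `*_cab` = Σ |sign(b)·LRT|) and common upstream TFs.

A synthetic-data generator with full ground truth (planted network, cleaved
TFs, misregulation profiles, proteome with planted cleavage sites, traits)
makes every stage testable without any external download.

## Worked example

```r
library(calpainGRN)

cfg <- sim_config(seed = 1)        # 20 TFs, 300 targets, 5 genotypes x 5 days x 3 reps
res <- run_pipeline(pipeline_config(synthetic = cfg, seed = 1,
                                    outdir = "run1"), quiet = TRUE)
print(res)
```

```
Pipeline run: run1
Signed regulatory network: 3200 edges, 20 regulators, 320 targets
  signs: 2110 activating (+), 1090 repressive (-)
  4 subnetworks (modularity 0.259)
  profiles: 155 activator-target, 56 repressor-target
Protease-controlled interactions: 1160 edges kept; 10 direct-target TFs, 211 indirect targets, 0 both
```

Reading this output: the inferred signed network keeps the top-10 inbound
edges per gene (320 genes × 10); Louvain finds four subnetworks at this
desk scale; the three mutant contrasts call 211 genes as consistent
activator/repressor targets; and the final filter identifies the 10 TFs
whose proteins carry NERD-like cleavage patterns and control misregulated
targets — on synthetic data these are exactly the 10 planted cleaved TFs
(the planted ground truth has 227 profile genes, of which 93% are
recovered at these noise settings). All tables are written under `run1/`
as TSV plus GraphML networks and a JSON ground truth.

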