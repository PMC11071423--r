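---
title: "Methods: fate-map aware analysis of paired single-nucleus multiome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fate-map aware analysis of paired single-nucleus multiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Reporter-based fate mapping marks cells by their transcriptional history: a
Cre recombinase driven from a developmental locus (here, *Rag1*) switches on
a tdRFP reporter that the cell and its progeny transcribe permanently.
Detecting the reporter transcript in single-nucleus RNA data therefore
classifies each cell as "experienced" (RAG_EXP) or "naive" (RAG_NAIVE) with
respect to that developmental program. When the same nuclei also yield ATAC
data, one can ask how developmental history rewires the *regulome* — the set
of chromatin regions whose accessibility co-varies with a gene's expression
across cells.

`fatemultiome` implements this analysis end to end: per-cell quality
control, lineage purging, reporter-based labelling, joint RNA+ATAC
clustering, three-assay marker discovery, peak-to-gene linkage with a
matched-background null, condition-split regulome comparison (including
UpSet-style exclusive intersections and "induced" peaks), motif deviations
and enrichment, and preranked GSEA. Because public data for this design are
not bundled, the package ships a synthetic paired-multiome generator with
planted ground truth; every statistical claim in the test suite is checked
against that truth or against an independent oracle.

# The peak-to-gene link (GPL) statistic

For a gene $g$ and a peak $p$ whose centre lies within $10^6$ bp of the
gene's TSS, the link score is the Pearson correlation $r_{gp}$ between the
TF-IDF-normalised accessibility of $p$ and the log-CP10K expression of $g$
across cells. Raw correlations are confounded by peak covariates
(GC content, overall accessibility, width), so each candidate peak is
compared against $n_{bg} = 200$ background peaks matched on those three
features (nearest neighbours in standardised feature space, excluding the
peak itself):

$$ z_{gp} = \frac{r_{gp} - \overline{r_{bg}}}{\mathrm{sd}(r_{bg})}, \qquad
   p = 2\,\Phi(-|z_{gp}|). $$

Links are retained when $p < 0.05$ and $|r| \ge 0.05$; a pair is tested only
when both the gene and the peak are detected in at least `min.cells = 2`
cells. Per-gene link counts, computed separately in each population, are the
"regulome activity" statistic; their difference (naive minus experienced)
ranks genes whose regulatory wiring depends on fate. "Induced" peaks are
those present in both naive conditions and in experienced cells under
disease, but absent from experienced steady state:
$(\mathrm{naive_{SS}} \cap \mathrm{naive_{AD}} \cap \mathrm{exp_{AD}})
\setminus \mathrm{exp_{SS}}$.

An important property of the matched background, visible in the simulated
data: a population-wide shift shared by many peaks (for example, all
naive-state-coupled peaks being more accessible in naive cells when links
are called across the whole dataset) is absorbed into the background
distribution and does *not* register as a link. The statistic is therefore
most sensitive when links are called within a population, which is how the
regulome comparison uses it.

# Tunable parameters

All tunables live in one configuration object (`default_run_config()`,
overridable from YAML/JSON via `read_run_config()`):

| group | parameter (default) | meaning |
|---|---|---|
| QC | `ns_max` 1.5, `tss_min` 1, `rna_min/max` 1,000/15,000, `atac_min/max` 100/75,000, `mito_max` 5%, `ribo_max` 10% | six strict per-cell gates |
| reduction | `n_pcs` 25, `lsi_dims` 2–25, `knn_k` 20, `cluster_resolution` 0.1 | embeddings, joint graph, Leiden resolution |
| markers | `marker_min_pct` 0.20, `marker_logfc` 0.25, `da_min_pct` 0.02, `nearest_gene_max_dist` 1e5 bp, `signature_top_n` 100 | detection/fold gates; DA-to-gene mapping |
| links | `link_window` 1e6 bp, `link_min_cells` 2, `link_n_background` 200, `link_p_cutoff` 0.05, `link_score_cutoff` 0.05, `link_min_cells_floor` 30 | the GPL statistic |
| GSEA | `gsea_min_size` 50, `gsea_max_size` 500, `gsea_p_cutoff` 0.05, `gsea_n_perm` 1000, `deg_min_pct` 0.1, `deg_logfc` 0.1 | set gates and ranking gates |

Notes on choices the method descriptions leave open:

* **Ribosomal criterion.** "Percent ribosomal" is implemented as the
  percentage of counts from `Rps`/`Rpl`-prefixed genes (not the fraction of
  ribosomal genes detected); both readings exist in the field, and the
  count-based one composes with the other count-based gates.
* **Reporter detection.** A cell is RAG_EXP iff the reporter count exceeds
  0; the threshold is exposed (`assign_fatemap(min_count=)`) because
  ambient contamination in real data may warrant a floor.
* **TSS enrichment geometry.** Mean per-base insertion coverage within
  ±100 bp of any TSS over the mean in two 100-bp flanks centred ±950 bp,
  pseudocount 1e-9; both fragment ends count as insertions. The flat-signal
  limit (uniform coverage → enrichment 1) is tested explicitly.
* **Normalisation.** Log-CP10K is the default variance stabiliser, with
  analytic Pearson residuals as an option. A regularised negative-binomial
  regression is deliberately not re-implemented: downstream statistics need
  a depth-invariant, roughly variance-stabilised matrix, not a particular
  fitting procedure.
* **Equal weighting.** The joint graph weighs the RNA and ATAC
  shared-nearest-neighbour similarities at a fixed 0.5/0.5 — "equal
  weighting" read literally, not per-cell learned weights.
* **Wilcoxon p-values.** Exact (tie-aware, by enumeration of group
  assignments) when the assignment count is small; normal approximation
  with tie/continuity correction otherwise.
* **DA to genes.** The top-100 DA marker list is deduplicated to genes
  (best p first) *before* truncation; distance is the bp gap between
  interval boundaries (0 on overlap), ties to the smaller start coordinate
  then the lexicographically smaller name.
* **GSEA p-values.** Significance uses gene-label permutation restricted to
  permutations whose enrichment score shares the observed sign:
  $p = (1 + \#\{|ES_{perm}| \ge |ES|\}) / (1 + \#\text{same-sign perms})$.
  A same-sign numerator over a total-count denominator is not null-uniform
  (it saturates near 0.5); the same-sign estimator is, and the suite checks
  uniformity against random sets.
* **Motif scanning.** PFMs become log2-odds PWMs with pseudocount 0.8
  against uniform base frequencies; a hit requires 80% of the maximum
  attainable score on either strand; `N` scores as background. chromVAR-style
  backgrounds use 10×10 GC × mean-accessibility quantile bins rather than
  full covariance matching — the same matched-null contract with simpler
  machinery.

# What the generator emulates — and what it does not

`default_paper_scenario()` builds a skin-draining lymph-node-like mixture:
2,000 cells across five types (ILC2 dominant, plus T, B, NK, DC), each split
by fate map and by disease state (steady state vs AD-like); per-cell depths
are log-normal (means 3,000 RNA / 2,000 ATAC counts); mitochondrial and
ribosomal genes carry realistic count shares; lineage-panel genes (*Cd3d*,
*Cd3e*, *Cd3g*, *Cd4*, *Cd19*, *Cd8a*, *Itgam*) are expressed in their
canonical types at rates tuned so the purge removes roughly half of each
non-ILC2 population (detection is Poisson, so removal $=1-e^{-\lambda}$);
the tdRFP reporter appears only in RAG-experienced cells with 20% dropout.

Peak–gene couplings are planted as shared per-cell gamma latents: in cells
of a link's active states, a latent $a_i \sim \Gamma(1.5, 1.5)$ multiplies
the peak rate by $e^{0.35 a_i}$ and the gene rate by $e^{0.3 a_i}$. The
scenario plants 100 naive-only couplings (two peaks per gene across 50
ILC2-program genes — regulomes with several links per gene), 12 "induced"
couplings (active in both naive states and experienced-AD, never
experienced-SS), 8 constitutive couplings, and a Th2-like 4-gene cytokine
block (*Il4*, *Il13*, *Rad50*, *Il5*) within one 200-kb window whose peaks
cross-link neighbouring genes through shared latents. Effect sizes were
chosen once for detectability at these cell numbers — the generative scale
of fate-map effects is not something the source analysis estimates — and are
documented here rather than fitted.

Two design constraints worth knowing about:

* **Type-marker peaks sit inside expression-flat genes.** Cell-type-specific
  peaks drive gene activity and differential accessibility for genes whose
  own expression is flat. If type-specific peaks sat next to type-specific
  genes, every such pair would be a genuine correlation within the linkage
  window and the planted-truth false-discovery accounting would be
  meaningless.
* **Composition effects are real and the generator exposes them.** Because
  per-cell depth is fixed, any population-specific extra rate mass dilutes
  all other features in those cells; an early scenario draft planted
  type-elevated linked genes and produced spurious negative gene–peak
  correlations through exactly this channel. The shipped scenario balances
  type rate mass so planted truth and null candidates are cleanly separated.

Not simulated (out of scope by design): doublets, ambient RNA, batch
effects or multi-sample integration, read-level sequences, realistic
fragment-size periodicity beyond a two-component sub-/mono-nucleosomal
mixture. Background fragments are uniform over the genome, so TSS
enrichment values are much larger than in real nuclei (flanks are nearly
empty); the QC gate behaviour, not the magnitude, is the tested contract.
Passing tests on this generator show the statistics recover the planted
structure under Poisson noise at realistic depths — not that they are robust
to the artefacts listed above.

# Numerical choices and degenerate inputs

* SVD/PCA signs are fixed by making each component's largest-|loading|
  feature positive, so embeddings are bit-reproducible.
* LSI component 1 is excluded from every downstream step (`lsi_dims` 2–25).
  On simulated data it is the component most correlated with sequencing
  depth (|r| ≈ 0.7, more than twice any retained component) — TF-IDF
  already removes most linear depth effect, so the near-perfect depth
  correlations sometimes quoted for raw LSI do not occur here.
* The logistic differential-accessibility fit is IRLS with a tiny ridge
  (1e-8, intercept unpenalised): well-posed fits match `glm` to ~1e-6;
  perfect separation stays finite and never yields `NaN`.
* Zero-variance genes or peaks are skipped as link candidates; peaks
  detected in no cell get all-zero TF-IDF rows; all-zero cells are an error
  for RNA normalisation and tolerated (as all-zero columns) for the derived
  gene-activity assay.
* Nucleosome signal with a zero sub-nucleosomal denominator is `Inf`
  (which the strict `< 1.5` gate then removes); TSS enrichment without any
  shared chromosome warns and returns 0.
* Cluster ids are contiguous from 0, ordered by decreasing size; Leiden is
  seeded and deterministic.
* Exclusive intersections assign every peak to exactly one combination;
  the 15 combination sizes always sum to the union size.

# Problem sizes

The test suite and the acceptance script run the full pipeline on the
~2,000-cell default scenario (547 genes, 426 peaks), a 500-cell calibration
scenario with 1,000 candidate pairs for the permutation null (200
permutations in the suite, 50 in the acceptance script), and 20 simulation
seeds for the clustering-recovery check. These sizes were chosen so the
planted effects are comfortably detectable and each property check completes
in seconds to a few minutes on one core.

# Known limitations

* The lineage purge removes any cell with a single lineage-panel count; in
  real data ambient contamination would make this gate too aggressive
  without an ambient-correction step, which is out of scope here.
* Bonferroni (the marker machinery's convention) is conservative for the
  DA assay's correlated peaks; BH is available via `p_adjust`.
* The matched-background null for links assumes enough peaks exist to
  match on (GC, accessibility, width); with very few peaks the sampler
  falls back to sampling with replacement and warns.
* GSEA set sizes are gated *after* intersecting with the ranked list, so
  permissive ranking gates materially change which sets are testable.
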