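---
title: "Models and methods behind picnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind picnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`picnet` infers physical cell–cell interactions (PCIs) in tumour
microenvironments from the biological doublets of droplet scRNA-seq and
characterises the transcriptional programs those contacts induce. This
vignette is the package's own account of the models, the assumptions they
rest on, the tunable parameters, and the numerical choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The pipeline at a glance

```
simulate -> qc -> deconv -> lda -> lrscore -> signature -> tf
```

Every stage consumes the previous one's in-memory results inside
`run_all()`; any prefix of the stage list is runnable, all thresholds are
`pci_config()` parameters with the standard defaults listed below, and all
randomness derives from one seed through `stage_seed()` (seed plus a fixed
per-stage offset, kept below 2^31).

## Quality control and normalisation

Cells and genes are filtered with the conventional droplet thresholds, all
exposed as parameters: genes detected in < 10 cells are dropped first, then
cells with totals outside [300, 5000] (inclusive — the bounds are stated as
a minimum and maximum), fewer than 200 detected genes, or a mitochondrial
fraction of 25 % or more ("below 25 %" read as strict) are removed. The
gene-then-cell order follows the order in which the criteria are usually
narrated; it matters only marginally because the gene filter rarely changes
cell totals at these scales. Normalisation is
`ln(1 + count / total * 10^4)` per cell. Highly variable genes are ranked
by the residual of the log variance from a 20-equal-occupancy-bin mean
trend, with zero-variance genes forced to the bottom and lexicographic
gene-id tie-breaks so the ranking is deterministic.

## Doublet deconvolution

The deconvolution follows the synthetic-doublet/random-forest recipe:
per-type marker genes are the top 100 by a one-vs-rest Wilcoxon rank-sum
z-statistic (tie correction included; ties broken by log-fold-change, then
lexicographically); synthetic doublets are elementwise sums of two distinct
sampled singlets for every homotypic and heterotypic type pair; a
500-tree random forest with sqrt(p) features per split (via `ranger`,
seeded, single-threaded for reproducibility) is trained on raw counts over
the marker union with equal numbers of singlet and synthetic-doublet
instances (the larger side is downsampled). Raw counts rather than
normalised values are used as features because a doublet's defining
property — roughly doubled totals with mixed marker content — is destroyed
by per-cell normalisation.

The enrichment score of a called doublet type is its observed count over
the count expected under independent pairing of singlet-type labels
(`2 p_a p_b` heterotypic, `p_a^2` homotypic), and the null distribution is
built from seeded simulations drawing the same number of label pairs. With
two or more samples, per-sample observed enrichments are compared to
per-sample simulated ones by a one-sided Wilcoxon rank-sum test; with one
sample an empirical p-value is used. Because type counts are small
integers, ties between observed and simulated enrichments are common and
the classical `(1 + #{sim >= obs})/(1 + n_sim)` estimate is visibly
conservative; the default is therefore the mid-p variant (ties counted
half), which keeps null p-values approximately uniform, with the classical
form available via `p_type = "conservative"`. Retained doublet types are
heterotypic with count >= 10 and p < 0.05, and per-group networks report
counts normalised by the group's cell number, scaled by 10,000.

## Two-stage topic modelling

The interaction-program extraction is a two-stage latent Dirichlet
allocation over integer gene counts (documents = cells, words = genes). No
LDA implementation ships with the package's R stack, so the variational
engine is implemented in the package (batch variational Bayes in C++,
symmetric priors `1/k`, linear-space E-step, convergence when the relative
score change drops below `1e-4` or after 200 passes; the per-document inner
loop stops at a mean absolute `gamma` change of `1e-3`).

*Stage 1* fits `k` topics to the cancer and stromal singlets. `k` can be
chosen by `perplexity_scan()` (default candidate range 2–20): held-out
cells are scored by document completion — the topic mixture is estimated
from a binomial half of each held-out cell's counts and perplexity is
evaluated on the other half — because full fold-in rewards overfitted topic
sets almost monotonically. Continuous perplexities never tie exactly, so
"smallest k on ties" is implemented with a relative tie tolerance (0.5 %).
The pipeline default is a fixed `k = 5`, commensurate with one topic per
major expression program of the two cell types across three clinical
groups; the scan is a config switch (`lda = list(scan = TRUE)`).

*Stage 2* fits `k + 20` topics to the cancer–stromal doublets with the
first `k` gene-topic columns taken from stage 1 and held fixed (they are
carried over bit-identically), so that whatever the singlet programs cannot
explain must be absorbed by the 20 free topics. Freezing is the
interpretation that makes "additional topics" well defined; a warm-start
mode without freezing is available (`freeze = FALSE`).

Two numerical choices matter here and were settled by experiment on the
generator (both are package parameters):

- **Initialisation of the free topics.** Against frozen, well-fitted
  singlet topics, a flat random start never wins a single token and the
  free topics stay empty; seeding them with whole doublet profiles instead
  makes them clone and absorb everything, including purely singlet
  content. The default therefore seeds each free topic with a *residual
  gene module*: each doublet is first scored under the frozen topics
  alone, the positive part of (observed − expected) counts is the
  unexplained expression, and k-means over the L2-normalised residual
  profiles of the top residual-carrying genes groups co-induced genes —
  an interaction program induced across many cells of a group is exactly
  such a module and seeds a single topic. An alternative stratified
  seeding (`seed_groups`, one topic per sample) is provided for data whose
  doublet-specific variation is organised by sample.
- **Candidate genes for the ranking.** Cells are assigned to the
  doublet-specific topic on which they place the most probability (the
  "highest probability score for each doublet topic"); near-duplicate free
  topics (cosine similarity of gene distributions > 0.9) are merged first,
  since a fit with more free topics than distinct programs necessarily
  produces duplicates. A gene is a candidate for a topic when its
  probability there exceeds its best singlet-topic probability at least
  `peak_ratio`-fold (default 2). A bare argmax (`peak_ratio = 1`) is
  extremely sensitive to sampling noise on flat genes: any gene whose
  fitted doublet-topic probability drifts marginally above its singlet
  probability becomes a candidate, and being ubiquitously detected it
  outranks genuine program genes under the cell-count ordering.

Candidates are then ranked per topic by the number of assigned cells
detecting them; genes seen in fewer than 5 cells are removed and the top 30
kept (probability tie-break, then lexicographic). Because the model sees
only counts, genes *silenced* by interaction can never surface in a topic —
directionality is recovered downstream by the signature stage, which is
also why signature recall against a truth containing fully silenced genes
is structurally capped (see the generator section).

## Ligand–receptor scoring

For each clinical group's cancer–stromal doublet cluster, `X_g^c` is the
mean normalised expression and `pct_g^c` the detection fraction. The
enrichment z-score standardises a gene across the group clusters,
`Z_g^c = (X_g^c − mean_c X_g^c) / std_c X_g^c`, with the population
(n-denominator) standard deviation by default — with only three cluster
means the choice is ambiguous, so it is switchable
(`sd_type = "sample"`) — and `Z = 0` when the std is zero, so flat genes
quietly fail the score filter instead of propagating NaN. The interaction
score is `sqrt(Z_L^2 + Z_R^2)` and a pair is retained per cluster iff all
five conditions hold: both means > 0, score strictly > 1.5, both detection
fractions >= 5 % (computed per cluster).

The second route calls ligand–receptor–pathway triples *active*. It is an
explicitly simplified surrogate for pathway-topology-based tools: target
sets come from user GMT files, the statistic per (pair, pathway with >= 5
targets present) is the Spearman correlation between ligand and receptor
and the mean Spearman correlation between receptor and targets across
observation units (pseudo-sample bins of doublet cells,
`make_expression_units()`), the permutation null shuffles the receptor's
values across units — which breaks both correlations simultaneously — with
the test statistic `min(rho_LR, rho_RT)`, and activity requires BH
q <= 0.01 with both correlations positive. One practical caveat is
inherent to permutation nulls under multiplicity: with `m` mostly-null
triples, a true signal can only survive BH if `1/(n_perm + 1)` is below
`0.01 * rank / m`, so `n_perm` must scale with the triple universe; the
pipeline default is 50,000 permutations for the ~400-triple desk-scale
universe (a few seconds, vectorised).

## Differential expression and signatures

Per-gene two-sided Wilcoxon rank-sum tests on normalised values, with BH
adjustment. When both groups have at most 8 cells the p-value is computed
by exhaustive enumeration of all group assignments (exact under ties);
otherwise the normal approximation with tie correction and continuity
correction is used. The log2 fold-change uses means of
`expm1`-transformed normalised values with a `1e-9` pseudocount
(switchable to plain normalised means). The doublet-specific signature per
group is the intersection of the group's LDA gene list with the genes
significantly up (or down) in doublets versus *both* the cancer and the
stromal singlets at adjusted p < 0.05; up- and down-sets are disjoint by
construction and their union is the combined signature.

## Transcription-factor activity

Counts are pseudobulked per (cell class × clinical group) — cancer
singlets, stromal singlets and cancer–stromal doublets over three groups
give the 9 pseudo-sample layout. Columns are CPM + log1p normalised before
scoring; unnormalised sums would confound activity with sequencing depth.
Each TF is scored by an ordinary least-squares fit of the expression vector
on its signed regulon weight vector (+1/−1 on targets, 0 elsewhere) with
intercept over all genes; the activity is the slope's t-statistic, computed
per TF via the closed form `t = r sqrt(n−2)/sqrt(1−r^2)` and capped at
`1e8` in magnitude for perfect fits. TFs keeping fewer than 2 targets after
intersection with the matrix are dropped. Contrast-level activity applies
the same model to the log2 fold-changes of the significant DEGs of a
doublet-group contrast. "Significant" for the top-25 selection means |t|
above the two-sided 0.05 critical value at the fit's degrees of freedom;
ties break lexicographically.

## The synthetic-data generator

`simulate_pci_dataset()` emulates a multi-patient, three-group (CR/PR/PD)
tumour dataset at desk scale. Defaults: 5 cell types (Cancer, Fibroblast,
Tcell, Macrophage, Bcell) × 2,000 genes; 20 markers per type elevated
8-fold over a shared gamma-distributed baseline; 3 samples (one per group)
with 1,500 singlets and 150 doublets each; negative-binomial counts with
dispersion 2 (a `nb_dispersion = Inf` switch gives the Poisson limit for
testing) and log-normal library sizes with mean 1,400 and CV 0.3 — chosen
so that doublets, being sums of two singlets, land inside the 300–5,000 QC
window as retained doublets do in real data. A configurable gene subset is
named with the `MT-` prefix so the mitochondrial filter is exercisable.

Planted structure, all on disjoint gene blocks that never overlap markers:

- **Doublets**: each is the elementwise sum of two sampled singlets from
  the same sample; 60 % are Cancer+Fibroblast by construction, the rest
  pair types drawn independently from the sample's singlet frequencies.
- **Interaction programs** (doublet-specific, per group): 30 genes
  multiplied 4-fold on the summed profile and re-drawn from the negative
  binomial; 10 genes zeroed. Unperturbed genes keep the exact singlet sum.
  Because down-genes are fully silenced they cannot appear in count-based
  topic models, which caps signature recall against the 40-gene truth at
  0.75 — a deliberate property that the acceptance threshold (0.6)
  accommodates, and a reminder that on real data partially silenced genes
  are the recoverable ones.
- **Ligand–receptor pairs with pathways** (group-level): 6 pairs (2 per
  group), each with an 8-gene downstream pathway. In the group's samples
  every cell carries a log-normal activity factor (sdlog 1.5) scaling
  ligand and receptor 3-fold and targets 2-fold — per-cell activity is
  what makes receptor–target correlation detectable across pseudo-sample
  units; dispersions much below 1 leave the correlation under the
  generator's own Spearman > 0.5 contract.
- **TF regulons** (group-level): 6 TFs × 20 signed targets (12 positive, 8
  negative); in the assigned group concordant targets are scaled up
  3-fold and discordant targets down 3-fold, with alternating planted
  activity signs.

TF and ligand–receptor effects are *group-level biology* applied in the
singlets and inherited by doublets through summation, so the interaction
programs are the only doublet-specific signal — mirroring the fact that
regulon activity differences between patients are not contact-induced. The
generator does not model batch effects, ambient RNA, UMI saturation or
spliced/unspliced structure; passing tests therefore demonstrate correct
recovery of planted structure under clean NB noise, not robustness to
those artefacts.

## Problem sizes and determinism

The test suite and the acceptance script work at the generator defaults
(≈ 4,950 barcodes × 2,000 genes) for end-to-end claims and at reduced
scales (a few hundred cells, 400 genes) for per-module properties; a full
pipeline run takes on the order of a minute on one CPU. Fixed seeds give
byte-identical artefact directories: every random operation derives its
seed from the single configuration seed, the forest is single-threaded,
and no stage reads hidden global state.

## Known limitations

- The enrichment-score null assumes independent pairing within (or
  pooled across) samples; structured capture biases would miscalibrate it.
- The LDA ranking can only surface genes expressed in doublets;
  direction comes from the DEG stage.
- `active_triples()` does not reproduce pathway-topology target
  extraction or regularised correlation shrinkage of dedicated
  bulk-communication tools; it is a correlation screen over user-supplied
  gene sets.
- With a single sample per group, group-level and sample-level effects
  are confounded by design — as they are in the motivating study design
  with one progressive-disease patient.
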