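---
title: "Methods: longitudinal 16S community dynamics, SparCC networks and co-abundance groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal 16S community dynamics, SparCC networks and co-abundance groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otudyn)
```

## The scientific setting

otudyn implements the analysis chain used to ask whether introducing a
single bacterial strain into a gut community accelerates a disease-driven
community collapse. The motivating design is a mouse colitis experiment:
three groups (vehicle control `PBS`, colitis induction by dextran sulphate
sodium `DSS`, and colitis plus oral gavage of a butyrate-producing strain
`DSS_BPB5`) sampled at days -1 (baseline), 2, 4 and 7, with per-cell sample
sizes (12, 10, 12, 6), (12, 12, 12, 6) and (12, 11, 12, 6) respectively —
123 faecal samples in all. The chain runs: paired-read quality control →
OTU table → rarefaction and diversity → Bray-Curtis ordination → PERMANOVA
screening → random-forest key-OTU selection → SparCC correlation network →
co-abundance-group (CAG) clustering → trajectory and differential
statistics.

Because the question is methodological — does the chain recover known
structure? — every stage is exercised against a synthetic generator whose
planted truth serves as the oracle. Nothing in the package depends on
downloading data.

## The synthetic community generator

`simulate_otu_table()` draws, per sample, latent log-abundances

\[ z_i = \mu_i + \delta_{i,g,d} + \sigma\left(\sqrt{\rho_b}\,F_{b(i)} + \sqrt{1-\rho_b}\,\varepsilon_i\right), \]

maps them through a softmax to fractions, and draws multinomial counts at a
depth uniform on 9,000–30,000 reads. This logistic-normal → multinomial
model is the standard compositional model and deliberately matches the
assumptions of the SparCC estimator downstream: correlation is planted on
the latent log scale (within 5 blocks of 10 OTUs, \(\rho_b = 0.8\) by
default, among 50 background OTUs), and the count space distorts it
compositionally — which is exactly what the estimator must undo.

Treatment effects are latent log-fold shifts \(\delta_{i,g,d}\) along a
linear ramp from day 0 to day 7 (two depleted blocks at \(-2\), one
enriched block at \(+2\) at the full ramp). The invader group experiences
the same ramp shifted three days earlier (`shift_lead_days = 3`), which is
what "accelerated dysbiosis" means here. The invading taxon is an extra
column, exactly zero in non-inoculated groups and before day 2, and
co-varies with the enriched block (its planted correlates) as an eleventh
block member.

Two generator parameters deserve comment:

* **Within-group noise** `sigma = 0.5` (natural-log scale, roughly 65%
  CV). This is the noise level at which the generator's own calibration
  contracts hold — rank tests recover log-fold-2 effects at n = 12/group
  with power above 0.8, and Benjamini-Hochberg-corrected testing recovers
  fold-4 effects with sensitivity above 0.9. It is plausible for inbred
  mice under controlled conditions; wild or human cohorts are noisier, so
  real-data power will be lower than what the tests demonstrate.
* **Sample sizes** are fixed to the study design; per-day animal attrition
  is not simulated. Dropout would mainly widen day-7 confidence intervals.

What the generator does **not** emulate: chimeras, primer artifacts,
taxonomy-realistic phylogeny, overdispersion beyond the logistic-normal,
or batch effects. Passing tests therefore demonstrate correctness of the
algorithms under a well-specified compositional model, not robustness to
every real-world artifact.

## Read quality control

The QC rules are deliberately literal: reads are truncated at the first
base with Phred quality at most 2; pairs must overlap by at least 50
bases; merged reads are kept only if at least 400 bases long ("longer than
399") with expected error \(\sum_b 10^{-Q_b/10} \le 0.5\). The merger is an
ungapped overlap scan choosing the offset with the most matching positions
(ties: longest overlap), with a 10% overlap-mismatch tolerance — indels in
the overlap of short-insert Illumina pairs are rare enough that gapped
merging buys nothing here. Within the overlap the higher-quality base wins
and its quality is kept (ties keep the forward base); this is intentionally
simple rather than a posterior-quality recalculation.

The read simulator plants qualities from a scenario mixture (clean pairs,
an early Q=2 crash, a long Q=13 tail, a dead first base) and computes each
pair's expected verdict **from the planted layout** — truncation points,
the true overlap offset, realized substitution errors, merged qualities —
without running the QC module's overlap search. Agreement between the two
is then a genuine two-sided check, and it is exact (100% over 1,000 pairs)
because both sides apply deterministic rules to the same planted data; the
only way they could disagree is if the overlap search picked a wrong
offset, which for 50+ base overlaps is vanishingly unlikely.

OTU construction follows the greedy centroid convention: dereplicate,
discard singletons, scan uniques in decreasing abundance, join the first
centroid at ≥ 97% global-alignment identity (matches / alignment columns,
terminal gaps excluded; Needleman-Wunsch with match 1, mismatch −1, gap
open 4, extend 1), then map reads back at the same cutoff with ties going
to the more abundant centroid. The identity definition and alignment
scoring are pinned parameters, exposed as arguments, because a 97% cutoff
is meaningless without them.

## Rarefaction, diversity, ordination

Samples under 9,000 reads are excluded; retained samples are subsampled
without replacement. Alpha diversity (observed OTUs; Shannon, base 2 by
default with the base exposed) is averaged over 1,000 repetitions (the
Monte-Carlo standard error of the mean Shannon is below 0.01 at that
setting); beta diversity uses the first seeded repetition, since averaging
count tables before Bray-Curtis has no standard definition and the choice
is exposed. PCoA Gower-centers the squared distances and drops negative
eigenvalues (reported, not corrected); PCA of relative abundances is
provided as PCoA of their Euclidean distances, which is mathematically the
same scores. The "variation from baseline" statistic is the mean
Bray-Curtis distance of each group-day's samples to the same group's
day -1 samples.

## PERMANOVA

One-way PERMANOVA partitions squared dissimilarities; the permutation p is
\((1 + \#\{F_\pi \ge F_{obs}\})/(n_\pi + 1)\), which cannot be zero and
includes the observed labelling. For tiny designs the full set of distinct
label assignments can be enumerated (`exact = TRUE`); the 4-point worked
example gives \(F = 18\), \(p = 1/3\). Permutations are of sample labels,
unstratified (stratification by day is a flag the screening layer does not
use by default, since the screened contrasts are within-day). The null
distribution is computed by a vectorized quadratic-form identity
(per-group indicator columns against the squared-distance matrix), which
is what makes 1,000-replicate calibration runs with 999 permutations cheap.
Group-pair screening is unadjusted at P < 0.05 — it is a gate for the
random-forest stage, not an inference in its own right.

## Random-forest key OTUs

For every screened-significant pair a 1,000-tree classification forest is
fit on relative abundances. A model "succeeds" only with out-of-bag error
exactly zero (the gate is exposed as `max_class_error`), and an OTU is
"key" when its unscaled mean decrease in accuracy exceeds 0.003 in at
least one successful model; the selection is the union across models with
provenance retained. The OOB-zero gate is what makes the procedure
conservative under the null: chance-level models (OOB ≈ 0.5) contribute
nothing, so label-permuted data yields an empty selection in ≥ 95% of
seeds.

## SparCC

Basis correlations are estimated from log-ratio variances
\(t_{ij} = \mathrm{var}\,\log(x_i/x_j)\): under the sparsity approximation
the basis variances \(\omega\) solve \(M\omega = t_{+}\) with \(M\) having
the count of non-excluded partners on the diagonal and 1 elsewhere, and
\(\rho_{ij} = (\omega_i + \omega_j - t_{ij})/(2\sqrt{\omega_i\omega_j})\),
clipped to \([-1, 1]\). Strongly correlated pairs (|ρ| > 0.1, up to 10
rounds) are iteratively excluded from the system, fractions are drawn from
the add-one Dirichlet posterior of the counts, and the element-wise median
over 20 such draws is reported (median rather than mean for robustness to
resampling outliers; both are options). Zeros are handled by the posterior
resampling itself. Significance uses the estimator's own null: each OTU's
counts are permuted independently across samples — resampling samples with
replacement would preserve correlation and cannot form a null — and
two-sided pseudo-p-values are computed over 100 such datasets, so the
smallest attainable p is 1/101. Networks draw edges at |ρ| > 0.5 with the
sign recorded.

## Co-abundance groups

Key OTUs are clustered by Ward linkage (Lance-Williams update on the
supplied dissimilarities) of \(d = 1 - \rho\) — not \(1 - |\rho|\), so
anticorrelated OTUs land in opposing CAGs, matching the biology of
disease-depleted versus disease-enriched guilds. The tree is cut top-down:
each node's two children are compared with the PERMANOVA pseudo-F on the
correlation-derived distances, and the split is accepted at p < 0.005
(9,999 draws maximum), recursing further; otherwise the node is one CAG.

The split test needs care, and this is the package's main deliberate
design choice. Comparing the observed pseudo-F against plain relabelings
of the node's OTUs is strongly anti-conservative, because Ward already
chose the split that maximizes separation — measured on structureless
correlation matrices, that naive test fragments pure noise into ~7 CAGs.
Shuffling the distances themselves is still anti-conservative (~70% false
splits), because correlation-estimation noise is Wishart-like and
orthogonally invariant, which clusters better than independent-edge noise
— and the pseudo-F is scale-free, so the noise level alone cannot save the
test. The null that works is a parametric bootstrap of the one-cluster
hypothesis: an exchangeable correlation matrix at the node's median
off-diagonal level plus Wishart noise at the effective sample size implied
by the MAD of the off-diagonal entries; each draw is re-clustered with
Ward and the pseudo-F of its best two-way split forms the null. Measured
behavior: structureless correlation matrices stay a single CAG in 20/20
runs, while five planted blocks are recovered with adjusted Rand index
1.0. Draws stop early as soon as p < alpha has become impossible, which is
what keeps 9,999-draw tests affordable. Accepted splits with a one-member
child produce singleton CAGs and recursion continues into the other child.

CAG abundance profiles are per-sample sums of member-OTU relative
abundances (conserving the key-OTU total), compared group-versus-reference
per day with Kruskal-Wallis and BH adjustment across the whole
CAG × day × group family. Invader correlates are the OTUs with
\(\rho > 0.5\) (or \(< -0.5\)) against the invader's row.

## Univariate statistics

Mann-Whitney U switches from the exact enumeration to the tie- and
continuity-corrected normal approximation at a combined n of 12 — the
study's cell sizes (6–12) straddle the regime where the approximation
degrades. Kruskal-Wallis uses the chi-square reference with tie
correction; all-identical inputs return H = 0 by convention rather than
0/0. BH adjustment is applied within each analysis family: across OTUs
within one contrast, and across the CAG × day × group table for dynamics.
Differential direction is the sign of the median difference against the
reference side.

## Pipeline, problem sizes, and determinism

`run_pipeline()` executes the stages in order, writes every intermediate
as plain text (TSV, Newick, GraphML, JSON summary), logs every parameter
and seed actually used, validates its config strictly (unknown keys and
missing seeds are errors), and can resume from cached per-stage results
without changing any output. All randomness flows through explicit seeds;
identical configs give byte-identical summaries.

The shipped checks run at deliberately desk-scale sizes chosen to estimate
each property tightly without waste: 1,000 read pairs for QC fidelity;
1,000 null replicates at 999 permutations for PERMANOVA calibration; 50
OTUs × 100 samples (and a 500-sample null) for SparCC; 20 seeds for CAG
and key-OTU recovery; 200 replicates for FDR control; and one full
123-sample end-to-end run with 100 rarefaction repetitions for the
trajectory logic. The end-to-end run reproduces the qualitative findings
the chain was built to detect: the invader group's mean Bray-Curtis
distance from its own baseline exceeds the plain-disease group's at day 4,
and at least one CAG reaches group-versus-control significance at an
earlier day in the invader group.

## Known limitations

* The sparsity approximation of the basis solve degrades when a large
  fraction of OTU pairs is truly correlated (e.g. two blocks covering all
  taxa); recovery contracts are stated for sparse-ish structure.
* The CAG split test's null is approximate — matched in level and noise
  magnitude, not in higher-order noise structure; its measured calibration
  is what justifies it.
* Greedy 97% clustering is order-dependent by construction (that is the
  convention it reproduces), and the alignment-parameter choices shift
  borderline identities.
* No phylogenetic diversity, no chimera detection, no taxonomy assignment:
  taxonomy strings are carried as optional labels only.
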