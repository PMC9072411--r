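---
title: "Scoring genetic interactions in dual-guide CRISPR screens across environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic interactions in dual-guide CRISPR screens across environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duoscreen)
```

## The experimental design being modelled

A dual-cassette CRISPR vector expresses one *S. pyogenes* Cas9 (SpCas9) guide
and one *S. aureus* Cas9 (SaCas9) guide from the same plasmid, so a single
infection knocks out two genes at once. A pooled library crossing every guide
in one position with every guide in the other yields all pairwise (and self-)
combinations; sequencing the cassette before (plasmid DNA, "pDNA") and after
a growth period in several media conditions measures each construct's fitness
in each environment.

The default design mirrors a family-wide mitochondrial transporter screen: 60
target genes with four guides per gene per enzyme, three positive-control
genes (BCL2L1, MCL1, EEF2) with two guides each, 8 non-cutting controls, and
19 cutting controls targeting olfactory receptors — 273 guides per position
and $273^2 = 74{,}529$ constructs. The 63 scored genes (targets plus positive
controls) give $63 + \binom{63}{2} = 2016$ gene-level perturbations, and
$2016 \times 4 = 8064$ gene-by-environment cells across four media
conditions (glucose, galactose, OXPHOS inhibition, no pyruvate). Guide
sequences are synthetic and seed-derived; nothing in the analysis depends on
their genomic identity.

## From reads to counts

Reads are parsed with an anchor/offset algorithm: the first occurrence of
`CACCG` (the vector sequence immediately preceding the U6-driven SpCas9
guide) marks the SpCas9 guide, which is matched exactly against the
reference (20 nt first, then 21 nt). The SaCas9 guide is located two ways —
as the 21-nt window starting 194 nt after the SpCas9 guide, and as the 21-nt
window following the *S. aureus* tracr anchor `CTTAAAC` — and only if the two
windows agree is the sequence looked up in the SaCas9 reference. The
reference may be truncated (`sa_match_length` < 21) to rescue reads with
degraded 3' quality; truncated prefixes shared by more than one guide are
ambiguous and are never assigned. The sample is read from the 8-nt barcode.
Every read is accounted for under exactly one status
(`assigned`, `no_sp_anchor`, `sp_unmatched`, `sa_mismatch`, `sa_unmatched`,
`barcode_unmatched`); counts-in equals counts-out is asserted, not assumed.

## Fitness and quality control

Per construct and endpoint sample,

$$\mathrm{LFC} = \log_2(\mathrm{CPM}_{\mathrm{condition}} + 1) -
  \log_2(\mathrm{CPM}_{\mathrm{pDNA}} + 1),$$

with CPM the counts-per-million within the sample and the pDNA reference
taken from the same batch. The pseudo-count keeps dropouts finite. Four
filters are applied in order, each removal attributed to the first
applicable step:

1. **Low pDNA representation.** Constructs below an empirical cutoff
   (default: the 1st percentile of the batch's pDNA counts; an absolute
   floor is available) are removed, as are all constructs containing a guide
   whose *median* pDNA count is below the cutoff.
2. **Non-cutting controls.** Cells carrying non-cutting guides escape
   double-strand-break burden and grow better than the population mean, so
   they are biased as a neutral reference; every construct with a
   non-cutting guide in either position is dropped. On the default design
   this removes $8 \times 273 + 273 \times 8 - 8^2 = 4304$ constructs — the
   one filter count that is determined by the design rather than the data.
3. **Lethal cutting controls.** A cutting control whose control-control
   constructs have a median LFC more than 3 robust standard deviations below
   the control-control centre (median/MAD) is treated as lethal and removed
   with all its pairs. The robust location/scale matter: with mean/SD the
   lethal constructs inflate the scale and mask themselves.
4. **Guide concordance.** Per gene and batch, each guide's profile — its
   LFCs against cutting-control partners, indexed by (condition, partner
   slot) — is correlated with the profiles of the gene's other guides
   (both positions). A guide whose correlation row-sum (self excluded) is
   negative is marked poor, and pairs containing any guide marked poor in
   any batch are removed. A profile built from all partners instead of
   cutting controls only is available (`profile = "all"`); the
   cutting-control profile is the default because it is the cleanest
   single-knockout readout.

After filtering, the pipeline verifies that no scored gene or distinct gene
pair lost all of its constructs (self-pairs are exempt: their interaction
score is identically zero, see below). Batches are stacked as replicate
observations — never averaged — and each construct carries its unordered
gene-pair key so that A×B and B×A orientations pool downstream.

## Gene-by-environment scoring

Single-knockout constructs (one scored gene, one cutting control) are
standardized within each condition and batch against the cutting
control-control distribution: $z = (\mathrm{LFC} - \mu_{cc}) / \sigma_{cc}$.
This makes the neutral phenotype 0/1 in every environment and removes
growth-rate differences between media. The regression

$$z \sim \mathrm{gene} + \mathrm{gene}{:}\mathrm{condition}$$

estimates each gene's fitness in the reference condition and a per-gene,
per-condition interaction coefficient; Wald p-values on the interaction
terms are Benjamini–Hochberg corrected across all gene × condition terms.
Hits are terms with $q \le$ `q_max` (default 0.05) and an absolute
coefficient of at least `min_delta_z` (default 1 z-unit). The thresholds are
parameters because the underlying study reports its hit count without
printing its cutoff; a robust median/MAD variant of the standardization is
available.

## Pairwise interactions: the constrained L1 additive model

For gene $i$ guide $j$ in the SpCas9 position and gene $k$ guide $l$ in the
SaCas9 position, the construct LFC matrix $C_{ijkl}$ is modelled per
condition as

$$(\hat\alpha, \hat\phi_{ij}, \hat\psi_{kl}) = \arg\min
  \sum_{ijkl} \lVert C_{ijkl} - \alpha - \phi_{ij} - \psi_{kl} \rVert_1
  \quad \text{s.t.} \sum_{i \in \mathrm{neg}} \phi_{ij} = 0,\;
  \sum_{k \in \mathrm{neg}} \psi_{kl} = 0,$$

where "neg" is the cutting-control guide set; the constraint pins the gauge
so that controls are the neutral reference. The interaction score of a pair
is the median residual over its guide pairs, pooling both orientations and
all batches:

$$\pi_{ik} = \mathrm{median}_{jl}\,(C_{ijkl} - \hat\alpha - \hat\phi_{ij} -
  \hat\psi_{kl}), \qquad \pi_{ii} = 0.$$

Negative $\pi$ is synthetic sickness, positive $\pi$ is buffering. Self-pairs
are set to 0 by definition (a construct cutting the same gene twice carries
no pairwise information); they are flagged in the output so they can also be
treated as missing.

**Numerics.** The L1 objective is minimized by iteratively reweighted least
squares with weights $1/\max(|r|, \varepsilon)$, $\varepsilon = 10^{-4}$,
solved per iteration as a sparse weighted normal system (Matrix) with a
$10^{-8}$ ridge for numerical stability; after each solve the
cutting-control means are subtracted from $\hat\phi$ and $\hat\psi$ and
absorbed into $\hat\alpha$, so the constraint holds exactly at every
iterate. Initialization is zero, making the fit deterministic. Iteration
stops when the largest parameter change falls below $10^{-6}$, when the raw
L1 objective plateaus (relative improvement $< 10^{-10}$), or at 200
iterations; a plateau counts as converged because the L1 surface is flat at
its optimum and parameter chatter there does not change the objective. The
test suite verifies the solution against an exact linear-programming oracle
on small instances (objective agreement within $10^{-6}$).

**Significance.** Per pair and condition, a one-sample moderated t-test of
mean guide-level residual ≠ 0: sample variances are shrunk across pairs by
empirical Bayes (limma's `squeezeVar`; prior df and scale estimated from the
variance distribution), the t statistic uses the posterior variance with
$df = n - 1 + df_{prior}$, and BH correction is applied within each
condition. With shrinkage disabled this reduces exactly to the ordinary
t-test. Pairs with fewer than 3 guide-level residuals are reported as
missing rather than scored.

## Condition-dependent interactions

Candidates are pairs significant at FDR < 2% in at least one condition.
Three disqualification rules, applied in a fixed order with the first match
recorded as the reason, remove artifact patterns:

- **small_effect**: $|\pi| < 0.25$ in every condition;
- **ceiling**: in a condition where the pair is significant, both genes have
  *positive* single-knockout effects yet $\pi < 0$ — the double knockout
  likely hit a growth ceiling rather than a real synthetic sickness;
- **deader_than_dead**: both genes are near-lethal (single-knockout LFC
  < −0.75) and $\pi > 0$ in all conditions — fitness cannot drop below dead,
  so the apparent buffering is a floor artifact.

A gene's single-knockout effect size is the median LFC of its guide ×
cutting-control constructs in the relevant condition (median for consistency
with the $\pi$ definition). Rule order affects only the recorded reason,
never membership. For reporting, $\pi$ is z-transformed within each
condition to correct for growth-rate blunting; the transformation never
feeds back into the rules.

## The simulator and what it does (not) emulate

Every stage is testable without external data because the package ships a
generative model of the screen:

- **pDNA abundance**: log-normal per construct (σ = 0.5) per batch,
  sampled with negative-binomial noise (default overdispersion 0.05, in the
  range typical of pooled screens; 0 gives Poisson).
- **Endpoint counts**: abundance re-weighted by $2^{\mathrm{true\ LFC}}$,
  renormalized to the sample depth, NB-sampled. The true LFC is
  $\alpha_c + \phi_{A,c}\,e_j + \phi_{B,c}\,e_l + \pi_{AB,c}\,e_j e_l$ with
  per-guide efficacies $e \sim U(0.8, 1)$ for targeting guides — efficacy
  multiplies effects, which reproduces the guide-to-guide LFC spread the
  concordance filter targets. Note the consequence: the estimator's estimand
  is the efficacy-attenuated interaction, so accuracy benchmarking uses
  `make_recovery_truth()`, which sets efficacies to 1.
- **paper_like truth**: knockouts mostly mildly deleterious; a per-condition
  severity multiplier (1 → 1.6) scales baseline effects — media swaps change
  a metabolic gene's fitness substantially, and this condition-dependent
  signal is exactly what the guide-concordance filter exploits; positive
  controls are strongly negative (they are dropout controls), with
  BCL2L1|MCL1 injected as the synthetic-lethal pair plus randomly chosen
  synthetic-sick, buffering and condition-specific pairs. `null` zeroes all
  effects including the non-cutting bonus.
- **Controls**: non-cutting guides get a +0.3 LFC growth bonus (no
  double-strand-break burden), reproducing why cutting controls are the
  better neutral reference; an optional fraction of cutting controls is made
  lethal (−4, near-complete dropout) to exercise the lethal-control filter.
- **Reads**: each read is barcode + `CACCG` + Sp guide + 194 nt of
  intervening vector sequence ending in `CTTAAAC` + Sa guide + suffix, with
  uniform substitution errors and a per-sample emission log for exact
  verification.

Not modelled: PCR jackpotting and chimeras, passage/bottleneck dynamics
(growth collapses into a single endpoint LFC), indels in reads, positional
biases. Passing tests therefore demonstrate correctness of the estimators
under a well-specified count-noise model, not robustness to every artifact
of real sequencing data.

A flat null screen deserves one caveat: with no condition-dependent signal
anywhere, the guide-concordance profiles contain only noise and their
correlation row-sums are coin flips, so on `null` truth the step-4 filter
flags guides at random. That is a property of the published rule, not of
this implementation; calibration runs therefore disable the
gene/pair-representation error (random guide removal does not bias
significance calibration).

## Problem sizes used in the validation suite

Accuracy is benchmarked at 20 genes × 4 guides per position with 19 cutting
controls, 2 batches, 4 conditions, mean depth 500 (interactions injected at
−1, −0.5, +0.5 on 12 pairs each): pi-score RMSE < 0.1 and Pearson r > 0.95,
pooled over a fixed three-seed set. Calibration uses ten null screens of 12
genes at depth 300: fewer than 5% of pairs are called at FDR < 2%, and the
gene-by-environment regression's false-call rate at q < 0.05 stays below 5%.
These sizes keep a full validation run around a minute on one core while
leaving every estimator in the regime it was designed for; the same
functions run the full 273 × 273 design in a few minutes.

## Known limitations

- Exact-match guide lookup only (configurable mismatch tolerance is
  reserved; the published algorithm implies exact matching).
- The read geometry implemented is the full-cassette layout the parsing
  algorithm describes; short barcode-pair-only reads are not supported.
- Self-pairs carry no interaction estimate by construction.
- The moderated test treats guide-level residuals within a pair as
  exchangeable; batch is not a covariate at that level (batches enter as
  replicates).
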