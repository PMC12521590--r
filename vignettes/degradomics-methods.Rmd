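---
title: "Methods: terminus mining, moderated statistics and the synthetic degradome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: terminus mining, moderated statistics and the synthetic degradome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degradomics)
```

## The problem

Shotgun proteomics of a trypsin-digested body fluid identifies peptides, most
of which have both boundaries explained by the digest: they start after a
lysine or arginine (or at the protein's database N-terminus) and end on K/R
(or at the database C-terminus). The minority of *semi-tryptic* peptides —
one tryptic boundary, one not — are informative precisely because trypsin
cannot explain the other boundary: it marks a protein terminus that already
existed in the sample, i.e. an endogenous proteolytic event. Cataloguing such
termini across a two-group cohort (for example, vitreous humor from retinal
detachment patients against surgical controls) turns a standard label-free
dataset into a degradome readout: which proteins are cut, where, how the two
groups differ, and which proteases plausibly did the cutting.

This package implements that desk analysis end to end, plus a synthetic
cohort generator with planted ground truth so that every stage can be
validated by recovery rather than by eye.

## Terminus calling

For an N-terminus the rule is: the residue flanking the peptide's N-boundary
(`prev_aa`) must not be K or R — otherwise the boundary is attributable to
the sample digestion and is discarded as an artifact. The called terminus is

* **mature** when the peptide starts at protein position 1 or 2 (the
  database N-terminus, position 2 covering initiator-methionine excision) or
  immediately after the annotated signal peptide (`start == signal_end + 1`),
* **neo** otherwise: evidence of cleavage of the mature protein.

The scissile bond is written P1↓P1′ with P1 = `start − 1`, matching the
convention in which a cleavage at `185↓186` leaves residue 185 as the P1 of
the cut. C-termini are symmetric: the peptide's last residue must not be K/R,
a peptide ending at the protein's last residue is the *database* C-terminus
(excluded from neo statistics — the mirror image of how database N-termini
are book-kept), and anything else is a neo C-terminus with P1 = `end`.

Three policy decisions that the calling rules do not themselves force:

* **Pure semi-tryptic evidence by default.** The boundary opposite the
  called terminus must be tryptic-compatible. A peptide with two
  non-tryptic boundaries is more likely a search artifact than two
  independent endogenous cuts; `allow_non_tryptic` relaxes this.
* **Start positions 1 and 2 both count as the database N-terminus.**
  Met-excision is near-universal and treating position 2 as internal would
  misclassify half of all database termini as neo.
* **Database N-termini are catalogued under `mature`** (a `db_terminus`
  flag retains the distinction for audit), keeping the downstream
  two-class mature/neo narrative.

Peptide-level identification confidence is applied before calling
(FDR ≤ 0.01 by default); rows that map ambiguously (several proteins, or
several positions) are skipped and counted, never silently used. Distinct
peptides that evidence the same (accession, P1) merge into one event:
presence vectors are OR-ed, per-sample intensities summed.

## Presence, exclusivity, Venn partitions

"Identified and quantified" means a non-missing raw intensity in that
sample; presence is counted **before** any imputation, because imputation
would fabricate presence. An event enters statistical testing when present
in at least 3 of 8 samples of at least one group (configurable). Exclusivity
is deliberately strict: `exclusive_<G>` requires presence in ≥ 50% (or 75%
for "group-specific" assignment) of group G *and zero* samples of the other
group. Venn partitions over any-sample group presence are disjoint by
construction and always sum to the number of features present in at least
one group — the pipeline asserts this rather than assuming it.

## Differential abundance

The intensity matrix (features × samples, log2, transformed exactly once —
the matrix carries a flag) passes through four stages in a fixed order:

1. **Class-specific quantile normalization.** Each group is quantile-
   normalized independently (each sample's observed values are replaced by
   the mean of the group's order statistics at the same quantile; ties
   averaged; missing cells stay missing). Normalizing within class avoids
   forcing the two groups onto a common distribution, which would erase
   genuine global differences; it presumes the groups are separately
   homogeneous, which the density plots of any given cohort should be used
   to check.
2. **CART imputation with predictive matching.** For each sample-column
   with missing cells, a regression tree predicts that column from all
   others on the rows where it is observed; each missing cell is dropped
   down the tree and receives a value drawn uniformly from the *observed*
   donor values in its terminal node. Columns are processed in order of
   increasing missingness, one sweep; a row whose predictors are all
   missing falls back to the root node (all observed values). Because
   donors are observed values, imputation cannot hallucinate intensities
   outside the data's support; because the draw is seeded, the completed
   matrix is reproducible. One imputation is performed (no pooling across
   multiple imputations) — a deliberate, simple default.
3. **Empirical-Bayes moderated t.** Per feature, the pooled two-sample
   variance $s_g^2$ (df $d_g = n_1+n_2-2$) is shrunk towards a prior
   $s_0^2$ with prior df $d_0$, both estimated by moment-matching the
   log-variances (digamma/trigamma inversion):
   $$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
     t_g = \frac{\bar x_{1g}-\bar x_{2g}}{\tilde s_g\sqrt{1/n_1+1/n_2}},$$
   with two-sided p-values on $d_0+d_g$ df. At $d_0=0$ this is exactly the
   ordinary pooled t-test (a tested identity); as $d_0\to\infty$ every
   feature is tested against the common prior variance. Borrowing variance
   across features is what makes 8-vs-8 designs workable.
4. **Storey q-values and threshold calling.** $\hat\pi_0 = \min(1,
   \#\{p>\lambda\}/(m(1-\lambda)))$ with a fixed $\lambda=0.5$ — the
   single-λ estimator is deterministic and robust at the feature counts
   involved, where the spline estimator is noisy. Calling is inclusive:
   **up** means log2FC ≥ +0.57 (1.5-fold) with p ≤ 0.05 *and* q ≤ 0.05 at
   the protein level; terminus-level lists use the p-value only
   (`dep_mode = "p"`), reflecting the lower power of terminus-level data.
   The fold-change threshold is symmetric (±0.57).

PCA variance fractions are reported over min(n−1, features) components of
the feature-centered matrix as a global separation diagnostic, and
over-representation of DEPs against user-supplied gene sets (GMT) uses the
hypergeometric upper tail with BH correction, reporting the gene ratio k/n.

## Cleavage-window profiling and protease attribution

Every interior scissile bond yields a ten-residue window P5…P1↓P1′…P5′,
`'X'`-padded where subsites fall outside the protein. Position frequency
matrices exclude the pad from each position's denominator, so edge-heavy
window sets do not dilute the logo. Group preferences are compared as
$\log_2((f_A+\varepsilon)/(f_B+\varepsilon))$ with
$\varepsilon = 1/(2\min(n_A,n_B))$ — half a count at the smaller sample
size — so residues observed in one group only remain finite; the comparison
is exactly antisymmetric in the groups.

Known-site annotation is an exact join on (accession, P1) against a local
cleavage-site table (off-by-one does not match); unannotated events are
`novel`. Protease enrichment builds, per protease, the 2×2 table of
annotated/not × foreground/background and applies the one-sided Fisher
exact test with BH correction across proteases. The default foreground is
the group-exclusive termini plus the termini significantly changed in that
group's direction; the background is the full called terminome of both
groups.

## What the synthetic degradome emulates

`simulation_config()` defines the cohort the generator produces; the
defaults *are* the validation conditions and are not adjusted per run:

* two groups of 8 samples; 100 proteins of 200–400 residues; 50% carry a
  signal peptide ending at residue 15–30;
* residues drawn uniformly over the 20 amino acids. This is deliberate:
  with flat composition, a protease whose acceptance probability is
  proportional to its positional preference produces accepted sites whose
  P1′ composition equals the planted preference *exactly* in expectation,
  so specificity recovery can be tested against a binomial reference with
  no compositional correction. (Real proteomes are not flat; on real data
  logos should be read against a background model.)
* three planted proteases, each with a 0.8 P1′ preference: glycine-directed
  (active in both groups), valine-directed (case-exclusive) and
  serine-directed (control-exclusive), at a per-site baseline rate of 0.01.
  A candidate site is accepted with probability
  $\min(1,\ \text{rate}\cdot e^{\text{score}})$, the score being the summed
  positional log-odds. The capped log link (rather than a logistic link) is
  what preserves the planted composition among accepted sites exactly; a
  logistic link compresses high scores and biases the recovered preference
  downward at usable rates.
* realized tryptic digestion with a 10% missed-cleavage rate per site;
  peptides of 7–50 residues; both flanking fragments of each planted cut
  are emitted (the N-side fragment starting at P1′ and the C-side fragment
  ending at P1);
* log2 intensities $\mathcal N(\mu_f + \delta\,[\text{case}], 1)$ with
  $\mu_f \sim \mathcal N(20, 2)$; a group effect of 2 log2 units on 10% of
  planted termini and on all peptides of 5% of proteins (random sign);
* missing-not-at-random cells via $P(\text{missing}) =
  \mathrm{logit}^{-1}(4.614 - 0.3\,x)$: ≈ 20% of cells overall, biased to
  low intensities. The intercept/slope pair was chosen by numerical
  integration over the intensity model so that the two stated conditions —
  overall missingness near 20% and near-complete recoverability of planted
  sites present at 0.9 per-sample occurrence — hold simultaneously; a much
  steeper slope concentrates missingness so heavily on the low-abundance
  tail that planted low-μ termini become unrecoverable in principle.
* decoy semi-tryptic rows (2% of tryptic rows) at uniform-random non-K/R
  boundaries, present in only 1–2 random samples: sporadic misassignments,
  the false-positive floor the presence filter is meant to remove.

Every row of the emitted report is traceable in a sidecar to exactly one of
{tryptic, mature, planted site, decoy}, and all randomness flows from one
master seed through stage-indexed substreams, so stage-level reruns
reproduce byte-identical outputs.

**What passing recovery does and does not show.** Recall/precision ≈ 1 on
this generator demonstrates that the calling rules, merging, presence
accounting and enrichment statistics are implemented correctly and hold
their nominal error rates under an MNAR missingness model. It does not
certify performance on real spectra: search-engine localization errors,
shared peptides between homologs and isoforms, ragged termini from
exopeptidase trimming, and non-flat residue composition are all outside the
generator and must be handled by the upstream search and by cautious
reading of real logos.

## Numerical choices and degenerate inputs

* All threshold inequalities are inclusive (≥ 0.57, ≤ 0.05), so boundary
  values are calls.
* Quantile normalization of a single-sample class warns and leaves the
  class unchanged; features missing in every sample are dropped with a
  warning before imputation; a column with no observed values is an error.
* A constant matrix is an error for PCA; all-zero-variance features are an
  error for moderation (nothing to moment-match).
* Tie handling: tied intensities receive the average of their tied
  normalization targets; tied p-values receive a common q-value through the
  step-down minimum.
* Degenerate specificity (temperature → 0) is numerically stabilized
  through a max-subtracted softmax, so "force residue X at P1′" works
  exactly.
* Empty stages propagate: a presence threshold no cohort can meet yields an
  empty terminome, an absent terminus-level DEA and empty enrichment, never
  a crash.

## Validation problem sizes

The shipped tests validate against independent oracles at sizes chosen to
keep the full suite around a minute: brute-force digestion enumeration on
200 random proteins (length ≤ 60, ≤ 2 missed cleavages); exhaustive
hypergeometric enumeration on a 10-element universe and tail sums for
N ≤ 30; 100 null replicates of 2 000 features × 16 samples for the type-I
sweep; 50 seeded cohorts each for the protease-recovery power and null
rates; and the default 100-protein cohort for end-to-end recovery. The
acceptance script (`scripts/acceptance.R`) recomputes the headline
quantities from scratch at the same sizes under a caller-supplied seed.

## Known limitations

Two-group designs only (no covariates, batch terms or multi-group
contrasts); exact-match peptide localization (no isoform-aware inference);
trypsin-only digestion rules (the classifier is parameter-free but the
digester ships trypsin only); single imputation; no spectrum- or
chromatography-level modelling; gene-set analysis is a generic
over-representation test with no ontology-graph semantics.
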