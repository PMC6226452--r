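---
title: "Screening conserved non-coding elements for lineage-specific divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening conserved non-coding elements for lineage-specific divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnescreen)
```

## The model

Conserved non-coding elements (CNEs) are genomic intervals under purifying
selection across a clade, frequently acting as *cis*-regulatory elements.
When a lineage loses a morphological trait, selection on the trait's
regulatory elements relaxes and their sequences decay at an elevated rate.
The screen detects this as *lineage-specific* divergence: a CNE whose
sequence identity to the reconstructed ancestor is far lower in the
trait-loss lineage than expected from that lineage's overall substitution
rate.

Three quantities drive the screen:

1. **Percent identity** of each species' CNE sequence to the ancestral
   sequence, reconstructed per column by marginal maximum likelihood under
   Jukes–Cantor with the input tree's branch lengths. Identity is a
   fraction in [0, 1]; 0 corresponds to complete loss of the element.
2. **Normalized identity** `seqId = (identity − 1) / d`, where `d` is the
   sum of branch lengths from the species to the ancestor. Division by `d`
   absorbs lineage-specific rate variation: a fast-evolving species is not
   mistaken for a diverged one. `seqId ≤ 0`, and 0 means perfect identity.
3. **Z-scores** `Z = (max(seqId_loss) − mean(seqId_others)) /
   sd(seqId_others)` with the sample (n−1) standard deviation. Taking the
   *maximum* over loss species is conservative: every loss species must be
   diverged for Z to be very negative. The *global* Z compares against all
   intact species; the *local* Z against designated close relatives, which
   excludes divergence shared by the wider clade. A CNE is called diverged
   when both Z-scores are strictly below the cutoff.

### Assumptions

* The alignment and tree are trusted inputs; no realignment is performed.
* Substitution follows a reversible single-nucleotide model. Reconstruction
  uses Jukes–Cantor; the simulator optionally adds a
  transition/transversion ratio (K80). Only the rate *contrast* between
  constrained and relaxed branches matters for the screen's behaviour, not
  the fine parameterization.
* Branch lengths are neutral rates; purifying selection is modeled as a
  uniform per-CNE rate scaling, not per-site rate variation.
* The comparison ancestor is the ingroup root; "distance to ancestor" is
  the leaf-to-root path length in the input tree.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `z_cutoff` | −3 | sd | three standard deviations below the intact-species mean, applied to both global and local Z with strict inequality |
| `min_nongap_frac` | 0.3 | fraction | a species with <30% non-gap characters over ancestral-base columns yields a missing value instead of a noisy identity; configurable because the threshold is a package choice, not a published one |
| `min_additional_species` | 3 | count | beyond the required loss/local species, at least this many further species must have data, limiting missing-data artifacts |
| `flank` / `min_length` | 50 / 30 | bp | coding intervals are expanded by 50 bp before subtraction (splice sites are conserved), and CNE remainders shorter than 30 bp are dropped |
| `max_gap` | 50 | bp | CNEs separated by a gap strictly smaller than 50 bp are merged before enrichment so clusters are not counted as independent observations |
| basal / extension | 5000, 1000 / 300000 | bp | GREAT-style regulatory domains: basal promoter window 5 kb upstream and 1 kb downstream of the TSS, extended up to the nearest foreign basal domain or 300 kb |
| `n_subsamples` | 10000 | draws | without-replacement subsamples of the CNE universe behind the enrichment Z-score |
| `pseudocount` | 0.01 | probability | added to each PWM cell before log-odds, bounding log ratios |
| `quantile` / `n_seqs` | 0.9 / 100 | — | motif cutoff: the 90% score quantile of 100 GC-matched random sequences with one inserted site |
| `n_ic_bins` | 20 | bins | equal-frequency information-content bins for the motif randomization control |

## The occupancy motif score

Motif content is scored with a closed-form occupancy statistic instead of a
two-state HMM: for each 200-bp window (step 100 bp) the score sums, over
every site position and both strands, `log2(1 + 2^llr)`, where `llr` is the
site's log-odds under the PWM against a GC-matched background; the sequence
score is the maximum window sum. The soft threshold `log2(1 + 2^x)` lets
strong sites contribute their full log-odds while weak sites contribute
proportionally less, so the score accumulates weak and strong occurrences,
makes no assumption about site position, and is robust to site turnover.
It is also exactly reproducible, which an HMM with unpublished transition
parameters would not be. Two numerical details:

* Window anchors are taken symmetrically from both sequence ends, making
  the score exactly invariant to reverse complementation for any sequence
  length (a left-anchored window grid alone would break the symmetry
  whenever the length is not a multiple of the step).
* Site positions containing N (or alignment gaps, which are stripped before
  scoring) contribute 0.

### Cutoff calibration and its sampling variance

The GC-dependent cutoff is calibrated per motif: for each GC bin in
0, 0.05, …, 1 (clamped to [0.01, 0.99] so sequences remain sampleable),
100 random 200-bp sequences receive one binding site sampled column-wise
from the PWM, are scored, and the cutoff is the smallest score such that
exactly `⌈0.1·n⌉` of the batch scores at least as high (the 91st order
statistic of 100). This convention makes "10% of the calibration batch
scores at least as high" literally true and centers the fresh-sequence
exceedance probability at 10/101 ≈ 9.9%.

A cutoff estimated from 100 sequences is itself random: its true tail
fraction is approximately Beta(10, 91), with a standard deviation near 3
percentage points. Calibration tests therefore compare pooled exceedance
rates against an interval that combines this order-statistic variance with
binomial noise of the fresh sets; a plain binomial interval would be far
too narrow for any implementation that calibrates from 100 sequences.

The ancestral-presence filter keeps CNE–motif pairs whose reconstructed
ancestral sequence scores strictly above the cutoff of the CNE's nearest
GC bin (ties between bins go to the lower bin). Note that a sequence
containing exactly one sampled site clears the filter only ~10% of the
time by construction — the filter selects ancestors with *more* motif
content than one average site, e.g. strong or multiple occurrences. The
package's end-to-end decay test plants two consensus sites per foreground
ancestor for exactly this reason.

## The synthetic-data generator

`generate_fixture_tree()` builds random binary trees with the trait-loss
species either as one nested clade (single loss, with its sister group as
the local comparison set) or scattered as sisters of different intact
species (independent losses). `evolve_cnes()` draws root sequences i.i.d.
from a configurable base composition, draws CNE lengths from a geometric
distribution truncated to [30, 1000] bp, and evolves each CNE along the
tree with per-branch expected substitutions `branch length ×
constrained_rate`, multiplied by `relaxation_factor` on branches whose
entire descendant leaf set lies within the loss species — for the planted
`relaxed_in_loss` fraction only. Truth labels are returned for every CNE.

The generator emulates what the screen needs: rate contrast between
constrained and relaxed elements on a known tree with known ground truth.
It does **not** emulate indels or alignment error (alignments are gap-free
by default, so identity reduces to mismatch counting), GC-content
heterogeneity along the genome, site-specific constraint profiles,
flanking coding/UTR context, or assembly artifacts. Passing calibration
tests therefore demonstrate the statistical machinery is correct under the
stated model, not that real-genome FDR estimates transfer: on real data,
alignment quality and missing sequence dominate the error budget.

Default study conditions for calibration runs: a 12-leaf tree (10 intact
species, 2 loss species in one clade), root-to-tip depth 0.5
substitutions/site, constrained rate 0.2, relaxation factor 20, 2,000
constrained plus 100 relaxed CNEs. These sizes keep the full simulation
suite to a few minutes while leaving expected null pass counts and
sensitivity measurable.

## Numerical and design choices

* **Identity scale.** Percent identity is a fraction; `(identity − 1)` then
  yields the documented negative seqId range.
* **Gaps.** A species gap (or N) opposite an ancestral base counts as a
  mismatch; ancestral-gap columns are excluded from the denominator.
  Ancestral gap status is decided by presence/absence Fitch parsimony with
  ties resolved towards a base; nucleotide ties are broken in the fixed
  order A < C < G < T.
* **Degenerate inputs.** Zero standard deviation among comparison species
  gives a missing Z (the record cannot pass); constant predicates make the
  subsampling Z undefined and raise an error; singular phylogenetic
  covariance skips that CNE with a warning.
* **Strictness.** All cutoffs are strict inequalities: Z < −3,
  ancestral score > cutoff, merge gap < 50 bp.
* **Branch association.** The published branch-based association for
  independent losses is implemented as a generalized least squares
  regression of species-level seqId on the loss indicator with
  Brownian-motion covariance from the tree and a one-sided p-value for a
  negative loss coefficient. This is a documented approximation: the
  original method operates on per-branch divergence changes, whose exact
  internals are published elsewhere.
* **Wilcoxon direction.** The excess-score test takes an explicit
  `direction` argument (default `"greater"`: foreground scores higher in
  intact species). The underlying publications describe both directions
  depending on the species considered, so intent is parameterized rather
  than guessed.
* **IC bins.** Equal-frequency (rank-based) bins are used for the motif
  randomization control; with as many bins as columns, randomization
  degenerates to the identity, which the tests assert.
* **Pipeline seeding.** One master seed is mixed with each stage name
  (`derive_seed()`), so stages are independently reproducible and rerunning
  any stage with the same config is byte-identical.

## Limitations

* Reconstruction accuracy degrades near the root for deep trees; the screen
  partially absorbs this because all species are compared against the same
  ancestor.
* The simulation null shares the screen's own substitution model, so the
  FDR estimate is a *model-based* calibration; the sister-lineage bound is
  the model-free complement.
* Fisher enrichment treats merged CNEs as exchangeable units; residual
  spatial correlation beyond 50 bp is not modeled.
* The occupancy score grows with sequence length within a window, so
  cutoffs calibrated at 200 bp are conservative for much shorter elements;
  comparisons across species of the same CNE are unaffected.
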