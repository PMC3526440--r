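---
title: "Binding loci from ancestral genomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding loci from ancestral genomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindingloci)
```

## The problem

Transcription factor binding sites (TFBS) are short (6--15 bp) and
degenerate, so scanning a genome with a position weight matrix (PWM)
produces mostly false positives. Phylogenetic footprinting improves
specificity by keeping only hits conserved across species, but it is blind
to *binding site turnover*: a new site arising near an old one can take over
its function, after which neither site looks conserved even though the
region never lost its ability to bind the factor.

`bindingloci` targets exactly this blind spot. Given a phylogeny whose
internal nodes carry *inferred ancestral sequences* (from an upstream
ancestral-reconstruction pipeline) aligned with the extant genomes, it asks,
window by window: has the **count** of predicted binding sites in this
region been preserved along the branches of the tree to a degree that
neutral sequence drift cannot explain, *given how diverged the sequences
actually are*? Windows where the answer is yes are **binding loci** --
regions that kept their binding capacity while their individual sites were
free to move.

## The predictor

A PWM is a column-stochastic 4 × w matrix. A length-w window s scores

$$\mathrm{LLR}(s) = \sum_{i=1}^{w} \ln \frac{p_i(s_i)}{q(s_i)},$$

against a background q (uniform by default -- composition-aware backgrounds
are deliberately out of scope, see Limitations). Both strands are scanned
and every window whose LLR *strictly exceeds* the per-factor threshold is a
predicted site; overlapping hits and both strands count separately, so a
palindromic site at one offset counts twice (a documented convention, not an
accident). Windows containing ambiguity codes are skipped, not scored.

The threshold is calibrated per factor by sampling 1000 sequences from the
PWM's own columns, scoring them, and taking the 10th-percentile score under
the nearest-rank definition (the ⌈n·p/100⌉-th smallest sample). With
strict-exceed semantics and tie-free scores this leaves exactly 900 of the
1000 samples above the threshold, i.e. the threshold is set so that ~90% of
sequences that look like genuine sites are accepted. Information content is
reported in bits; LLRs are natural-log internally -- only ranking and
thresholds matter, so the base is a free choice.

Defaults worth knowing: pseudocount 0.01 per matrix cell before
normalisation (prevents −∞ scores), uniform background, seed-controlled
sampling everywhere.

## The neutral model

Let $B(s)$ be the predicted-site count in sequence $s$. For each branch
(parent $p(u)$, child $u$) of the tree and each reference window $W$, the
aligned parent/child rows give a divergence estimate
$\lambda = \mathrm{round}(100\,(1 - \mathrm{PID}))$ -- integer percent,
half-up rounding, with gap and ambiguous columns excluded from the identity
denominator so indels are not double-counted as mismatches. Rather than
deriving $\Pr[B_{child}=b \mid B_{parent}=a, \lambda]$ from an explicit
substitution/indel model, the package estimates it *empirically*: every
(window, branch) pair in a large set of non-overlapping windows contributes
one $(\lambda, a, b)$ observation, and normalised counts within each
$(\lambda, a)$ cell are the transition probabilities. Estimating from the
same alignments that are later scanned means misalignment and
ancestral-reconstruction error are absorbed into the null rather than
mistaken for signal. The small contamination by genuinely functional windows
biases the null toward conservation, which only makes the final predictions
conservative.

Numerical choices, all configurable:

* **Divergence pooling** (`min_obs`, default 50): for a given parent count
  $a$, integer-percent divergence bins are merged with their nearest
  neighbour (walking upward in $\lambda$) until each pooled cell holds at
  least 50 observations. Tail probabilities -- the p-values -- are
  meaningless in nearly-empty cells; pooling trades divergence resolution
  for tail stability. Divergences outside every pooled range fall back to
  the nearest pool.
* **Count cap** (`a_cap`, default 20): counts at or above the cap share one
  bin; windows with dozens of hits are rare and usually repeat-driven.
* **Additive smoothing** (`smooth`, default 0.5): within each cell, every
  child count in the support $[0, \max(b)+2]$ receives 0.5 pseudo-
  observations (the Krichevsky--Trofimov estimator for a categorical
  distribution). This matters more than it looks: the p-values live in the
  tails, and a tail outcome that simply failed to appear among ~50 cell
  observations plausibly has probability of order $1/n$ -- a fixed tiny
  floor (say 1e-4) would understate it ~50-fold, and one such understated
  branch contributes a $-\ln p \approx 9$ spike that by itself pushes a
  neutral window past any reasonable significance cutoff. Additive
  smoothing estimates unseen outcomes near $0.5/n$, keeping the locus-level
  type-I rate at or below its nominal level. An observed count beyond the
  smoothed support gets the cell's smallest positive mass instead of zero.

## Branch p-values and the locus score

For an observed branch with parent count $a$, child count $b$ at divergence
$\lambda$, the conditional p-value is the one-sided tail

$$p = \Pr[\,\Delta_{neutral} \ge \Delta_{observed}\,]
    = \sum_{b' \ge b} \Pr[b' \mid a, \lambda],$$

with both count changes oriented child-minus-parent: preserving or gaining
sites is what a neutrally drifting window rarely does, so that is the
surprising tail. Losing all sites gives $p = 1$ by construction. (The
opposite orientation for the observed change -- which would make losses look
surprising -- is available behind `literal = TRUE` for comparison, but it
contradicts the quantity the method is meant to measure, preservation, and
is not the default.) Conditioning on the *observed* divergence is a
deliberate design choice with a known cost: perfectly conserved regions
(λ = 0) can never look surprising, because the λ = 0 cell says neutral
sequences at zero divergence keep their counts too. The benefit is that
regions conserved for unrelated reasons (e.g. a non-coding RNA) do not flood
the predictions.

Per-branch p-values are rarely small on their own; the evidence accumulates
over the tree:

$$\mathrm{BindingLocusScore}(W) = -\sum_{u \ne root} \ln\, p_u,$$

where branches with missing data or unsupported conditions simply drop out
(they are recorded, not imputed). The score's null distribution is computed
*exactly up to binning*: each branch condition $(\lambda, a)$ induces a
discrete distribution of $-\ln p$ over the possible outcomes $b$, these are
binned at 0.05 (in $-\ln p$ units) and convolved across branches. The null
is rebuilt per window from that window's actual branch conditions -- the
p-value distributions are condition-specific, so a single global null would
be wrong -- with caching over repeated condition multisets. Significance is
$\Pr[\text{null} \ge \text{observed}]$ with the observed per-branch
contributions discretised on the same bin grid as the null's: both sides
truncate each branch's $-\ln p$ identically, so sub-bin remainders
accumulated over many branches (sixteen branches each contributing a
negligible 0.006 would otherwise sum past the first bin) can never make an
unsurprising window look significant. A score beyond the null's support is
floored at the smallest positive bin mass, never zero.

The genome is scanned with 200-bp windows at 20-bp offsets (both
configurable; 200/20 are the defaults the method was designed around).
Overlapping significant windows are merged into maximal runs -- reported
alongside the per-window list, since either may be the more useful unit --
and the member TFBS of significant windows are reported from the reference
sequence only: ancestral hits inform the score but are not themselves
predictions.

## The simulator

Because the real inputs (multi-genome alignments with inferred ancestors)
are bulky and carry no ground truth, the package ships a generator that
makes the whole pipeline testable end to end. Sequences evolve from a root
along a user-supplied tree under an HKY-style substitution process
(transition/transversion ratio 2, rate matrix scaled to one expected
substitution per site per unit branch length) plus insertions and deletions
at one tenth of the substitution rate each, geometric lengths of mean 2.
Homology is tracked exactly through real-valued column keys, so the emitted
alignment is the *true* one; an optional corrupter re-places gaps within
local chunks to emulate aligner error while preserving every sequence.

Planted binding loci implement the turnover narrative mechanically:
selection acts on the *count* of predicted sites in a coordinate-tracked
window -- proposed mutations that would drop the count below k are rejected
and redrawn -- so individual sites are free to be destroyed whenever a
compensating site exists. The defaults (9-leaf tree with branch lengths
giving per-branch divergences of roughly 5--15% at scale 1, 200--400
windows per experiment, k = 2) are the regime the method is designed for;
detectability checks use tree scale ~2, putting per-branch divergence in
the 15--30% band where turnover is realised but signal survives.

What the simulator does *not* emulate: GC heterogeneity and composition-
matched selection, duplications and rearrangements, context-dependent
substitution, realistic mammalian branch lengths, and ancestral-
reconstruction *bias* (its alignments are true unless corrupted). Passing
tests on simulated data therefore demonstrate internal correctness and
calibration of the statistics, not performance on real genomes.

## Problem sizes and verification

The test suite verifies, among others: exact agreement of the scanner with
an independently coded naive scorer; the 900-of-1000 calibration law; exact
tail identities of branch p-values on hand-built tables; agreement of the
convolution null with 1e5-draw Monte-Carlo sampling (KS < 0.01 on the bin
grid); type-I control of locus p-values on fresh neutral data (1000
training + 1000 test windows, ≤ 7% at α = 0.05 -- discreteness and
conservative binning keep the realised rate below the nominal level);
recovery of 10 planted loci among 400 neutral windows into the top 5% of
the score ranking across seeded replicates; and the drift property that the
probability of retaining two sites decreases with divergence and is lower
for an 18-bit motif than a 10-bit one at matched divergence. These sizes
were chosen as the smallest at which the stochastic properties are stable.

## Limitations

* The null is per-factor and composition-blind; GC-rich factors scanned in
  GC-shifted regions will be mis-calibrated (a composition-stratified null
  is the natural extension).
* Ancestral counts use a single reconstructed sequence, not the posterior
  over ancestral sequences; uncertain ancestors are treated as certain.
* Highly conserved regions are structurally penalised by the conditioning;
  for factors whose sites sit in deeply conserved enhancers, plain
  conservation filtering will outperform this method.
* Raw per-window null p-values and ranks are reported; no multiple-testing
  correction is applied across windows.
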