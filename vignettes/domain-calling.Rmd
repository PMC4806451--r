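---
title: "Calling broad domains and narrow peaks with a two-state Gaussian HMM"
author: "domainHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling broad domains and narrow peaks with a two-state Gaussian HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

ChIP-seq enrichment comes in two shapes: multi-kilobase *broad domains*
(histone marks such as H3K27me3 or H3K36me3 covering whole gene bodies)
and sub-kilobase *narrow peaks* (transcription factors bound at discrete
sites).  Most callers specialize in one shape and must be re-tuned — or
swapped out entirely — for the other.  domainHMM calls both
simultaneously: it segments binned, control-normalized read counts with a
two-state hidden Markov model whose states represent "enriched" and
"depleted" chromatin, and reports per-bin posterior probabilities so users
can choose the confidence level they act on.  A companion refinement step,
`peakCenters()`, recovers base-pair resolution for narrow sites that
binning necessarily blurs.

## The model

For one chromosome, let $O_{1:B}$ be the observations in its $B$ retained
bins and $S_{1:B} \in \{\text{depleted}, \text{enriched}\}^B$ the hidden
states.  The joint likelihood given parameters $\Theta$ is the standard
HMM factorization

$$
P(O_{1:B}, S_{1:B} \mid \Theta) =
P(S_1)\,P(O_1 \mid S_1)
\prod_{b=1}^{B-1} P(S_{b+1} \mid S_b)\, P(O_{b+1} \mid S_{b+1}),
$$

with Gaussian emissions: one $N(\mu_j, \sigma_j^2)$ per state.  The
Gaussian choice reflects what control-subtracted, depth-normalized bin
counts actually look like at sequencing depths in the tens of millions:
an approximately normal null centered on 0 with standard deviation around
5, plus a long right tail from genuine enrichment.  The model makes *no*
assumption about read geometry around binding sites (no strand
cross-correlation, no fragment model), which is exactly why it handles
broad and narrow enrichment with the same machinery.

### Preprocessing (what the observations are)

1. **Binning.** Mapped, primary, non-supplementary alignments with
   MAPQ ≥ 30 are counted into uniform bins (default 1 kb) by their
   0-based leftmost aligned coordinate.  The MAPQ cut drops multi-mappers
   and poor alignments, which implicitly removes unmappable regions from
   the analysis.  Counting by read start (rather than any-overlap) counts
   each read exactly once, deterministically; at 1 kb bins and ~50 bp
   reads the difference is cosmetic.
2. **Depth normalization.** Both datasets are scaled to
   `raw * divisor / total`, with one shared divisor keyed on the smaller
   dataset: totals below 1e7, 1e8, 1e9 reads select divisors 1e6, 1e7,
   1e8 (continued in powers of ten beyond that).  The shared divisor keeps
   ChIP and control on one scale before subtraction.
3. **Subtraction and zero-bin exclusion.** Observations are normalized
   ChIP minus normalized control, restricted to bins with at least one
   raw read in either dataset.  Read-free bins carry no evidence — they
   are typically unmappable — and are excluded rather than imputed; they
   also break domain contiguity downstream (`bridgeGaps` relaxes this).
4. **Truncation.** Values are clamped into `[minCount, maxCount]`,
   default `[-10, 200]`.  Repetitive regions otherwise inflate the fitted
   variances.  The defaults are calibrated to the ≈5 null standard
   deviation of deep datasets: −10 allows two standard deviations of
   depletion, 200 (= 40σ) caps pile-ups while leaving real enrichment
   room to skew right.  Without a control the floor is 0, since raw
   normalized counts cannot be negative.

**Scaling the truncation to depth.**  The bounds are *scale* parameters:
they only make sense relative to the null standard deviation
$\sigma_0 \approx (\text{divisor}/T)\sqrt{\lambda_t + \lambda_c}$, where
$T$ is the total and $\lambda$ the per-bin background count.  At desk
scale (say 1e5 reads over 4 Mb) the per-read quantum $\text{divisor}/T$
is ≈11 and $\sigma_0$ is ≈70, not 5, so applying `[-10, 200]` literally
would clip half of the null distribution.  The package's own synthetic
validation therefore uses bounds at the *same multiples* of its
$\sigma_0$ that the defaults represent at depth — e.g. `maxCount = 3000`
(≈40σ) and `minCount = -300` for the 200k-read validation genome.  Users
with unusually shallow or deep data should do the same arithmetic; the
run report prints the divisor and totals needed for it.

### Fitting

Parameters are estimated **per chromosome** by Baum–Welch EM.  Chromatin
state composition differs across chromosomes, and per-chromosome fits
proved slightly more sensitive and specific than one genome-wide fit; the
price is that a rare chromosome may fail to converge, in which case the
driver substitutes the element-wise **average of the other chromosomes'
converged parameters** (aligned so "enriched" averages with "enriched")
and notes it in the run report.

* **Initialization.** Depleted state: empirical mean and SD of the
  observations.  Enriched state: three times the empirical mean, same SD.
  Prior 0.5/0.5; self-transitions 0.9 (domains persist across bins, and
  EM updates transitions from the first iteration anyway — only emission
  initialization materially steers which basin EM lands in).
* **Convergence.** Stop when the log-likelihood improves by less than
  1e-4, cap 500 iterations — ordinary EM settings, overridable.  The
  log-likelihood trace is retained and is non-decreasing up to 1e-8; the
  test-suite asserts this on every fixture.
* **Restarts.** If a fit fails (including emission-SD collapse below
  1e-6, which signals a state latching onto near-duplicate values), the
  fitter retries up to three times with emission means perturbed by one
  empirical SD, drawn from a fixed seed ladder so runs are reproducible.
  One correct EM implementation with restarts replaces the two-library
  fallback an R user might otherwise improvise; when two correct
  implementations both converge they agree anyway.

### Numerical choices

The forward recursion is scaled: each step's forward vector is divided by
its sum and the log of the sums accumulates the log-likelihood, which
prevents the underflow an unscaled product of densities hits within a few
hundred bins.  One extra guard matters in truncated data: an observation
can sit so far into *both* states' tails that both densities underflow to
zero.  Emission densities are therefore computed in log space and
row-shifted so the larger of the two is exactly 1 before exponentiation;
the shift is added back into the log-likelihood.  This makes the
recursions immune to outliers without changing their values.  The
backward pass and the transition posteriors reuse the same shifted
densities, and the E-step's transition sums are computed vectorized over
bins.

### Label resolution and decoding

An HMM's state indices are arbitrary: EM converges equally happily to the
mirrored labeling, and acting on the wrong label inverts every call —
enriched reported as depleted.  After fitting, the enriched state is
identified as **the state capturing the higher variance** (enrichment is
right-skewed, so the enriched state absorbs the spread); exact variance
ties break toward the larger mean.  The test-suite includes a label-swap
invariance check: fitting from mirrored initializations yields identical
final calls.

Each bin then gets its **smoothed marginal MAP state** — the
forward–backward posterior, not the Viterbi path — because the posterior
itself is the product's confidence currency: the BED output shades each
bin by it (black above 0.9, greys `120,120,120` above 0.8 and
`180,180,180` above 0.7 — the exact grey levels are a display choice).
Exact 0.5 ties decode as depleted, the conservative direction.  Domains
are maximal runs of consecutive enriched bins with posterior above
`minPosterior` (default 0.9, the black tier), each labeled with the
minimum posterior among its bins — the confidence of its weakest link —
and clamped to chromosome bounds.

### Peak refinement

`peakCenters()` replaces each called region with a fixed-width interval
(default ±100 bp, i.e. 200 bp) centered on its per-base coverage maximum,
computed from the same MAPQ-filtered reads as binning.  Coverage plateaus
tie-break to the midpoint of the leftmost maximal plateau — symmetric and
deterministic; an all-zero region falls back to its midpoint with a
warning.

## The synthetic validation data

Two generators make every stage testable without downloads:

* `simulateObservations()` draws observation series directly from a
  specified HMM.  The defaults used throughout the tests — depleted
  $N(0,5)$, enriched $N(15,5)$, self-transitions 0.95 — reproduce the
  scale of control-subtracted data at real depth, so EM is exercised on
  exactly the distributions the model assumes.
* `simulateTruthSet()` / `simulateReads()` build a read-level fixture:
  two 2 Mb chromosomes; five non-overlapping 10–50 kb domains placed on
  the 1 kb bin grid (grid alignment makes base-level truth accounting
  unambiguous), each containing one summit; 8× treatment enrichment over
  uniform background; 100k treatment + 100k control reads of 50 bp; 10%
  of reads at MAPQ 10 to exercise the filter; summits as 400-read
  Gaussian pileups (SD 15 bp).  Reads are emitted as sorted, indexed BAM.

On this genome the full pipeline at `minPosterior = 0.9` recovers ≥90% of
planted enriched bases with ≤1% of background called (in practice 100%
and 0% across seeds), and every summit within ±100 bp (in practice within
a few bp).  `scripts/acceptance.R` recomputes these numbers from scratch.

**What passing these tests does and does not show.**  The generators are
Poisson-uniform: no GC or mappability bias, no duplicates, no fragment-
length structure, no overdispersion beyond the planted signal, and
enrichment that is piecewise-constant rather than tapering at domain
edges.  They validate the algorithmic contract — normalization
arithmetic, EM correctness against exhaustive enumeration, inversion
robustness, coordinate handling — not performance on biased real
libraries, where specificity hinges on a matched input control.

Problem sizes were chosen to make each check sharp but cheap: exhaustive
path enumeration up to $B = 8$ (256 paths), EM recovery at 5000 bins over
five seeds (sampling error well inside the ±1.0 mean / ±0.03 transition
tolerances), and the 4 Mb / 200k-read genome above for the end-to-end
run.

## Known limitations

* Two states only: co-occurring weak and strong enrichment in one
  chromosome is absorbed into the enriched state's variance rather than
  resolved into levels.
* A bin is the resolution floor for calling; `peakCenters` sharpens
  centers but not boundaries.  For boundary-critical narrow-peak work at
  high depth, a smaller `binWidth` (e.g. 200 bp) is the right knob.
* The no-control path cannot distinguish enrichment from mappability or
  copy-number artifacts; a matched input is strongly recommended.
* Truncation bounds are depth-relative (see above); defaults assume
  tens of millions of reads on a mammalian-scale genome.
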