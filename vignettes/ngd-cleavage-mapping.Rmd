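---
title: "Methods: stall-relative cleavage mapping and kinetic quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stall-relative cleavage mapping and kinetic quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngdmap)
```

# The model

No-go decay responds to a stalled ribosome with an endonucleolytic cleavage
of the mRNA upstream of the stall. The geometry of the reaction is set by the
ribosome queue: the stalled lead ribosome protects ~15 nt of mRNA 5′ of the
stall, and each trailing (collided) ribosome protects ~30 nt more, so
candidate cleavage positions — ribosome boundaries — sit at stall-relative
distances

$$d_k = \ell + (k - 1)\,f, \qquad k = 1, \dots, K$$

with lead footprint $\ell = 15$ nt, trailing footprint $f = 30$ nt and queue
depth $K$. `ngdmap` encodes this as a `queue_model` with two regimes:

* **static** — the queue persists (rescue-proficient cells, inefficient
  cleavage): each event fires boundaries independently with probability
  `cleavage_prob`, and by default only the most-3′ fired boundary leaves a
  fragment. When firing is stochastic, fragments accumulate across the whole
  ladder and the inter-peak spacing equals $f$ (the ~30-nt periodicity
  regime). The `keep_all` diagnostic mode records every fired boundary of
  every event, exposing the full ladder deterministically; it is the natural
  setting for end-to-end recovery tests with `cleavage_prob = 1`, where the
  winner-takes-most-3′ rule would otherwise collapse all events onto $d_1$.
* **iterative** — each cleavage creates a new mRNA 3′ end; without rescue
  the next ribosome runs to that end, stalls, a fresh queue forms and the
  next cut lands $\ell + f = 45$ nt further upstream. Successive cuts on one
  molecule therefore recede by 45 nt (the widened 40–60-nt spacing regime
  seen when rescue is disabled; the model idealises it at exactly
  $\ell + f$). A molecule's run of cycles ends when a cycle fails
  (probability $1 -$ `cleavage_prob`) or when the cut would fall before
  position 1, and a new molecule starts at the stall.

The simulator makes no claim about exonucleolytic nibbling of fragment ends
before adapter ligation; a uniform `jitter` (± nt, default 0) is available
to emulate end heterogeneity without asserting a mechanism.

Fragment 3′ ends are observed by 3′-RACE: an adapter
(`CTGTAGGCACCATCAAT`) is ligated to RNA 3′ ends, and libraries are amplified
with a reporter-specific 5′ primer. `synthesize_reads()` mirrors this
construction: each read is the reporter subsequence from the primer to its
cleavage site, 5′-truncated to the read-length budget (the 3′ end, which
carries the information, is always retained), with the adapter appended
except for a configurable ligation-failure fraction, then independent
per-base substitution errors. Sites 5′ of the primer are unamplifiable and
must be filtered by the caller — `synthesize_reads()` refuses them loudly
rather than silently dropping signal.

# Coordinates

All user-facing coordinates are 1-based and inclusive. A reporter carries a
`stall_start` (the printed insertion coordinate of the stall element — for
the canonical layouts, 1040 for the stem loop and 950 for the codon runs — is
used directly as the reference nucleotide) and a `primer_start` (585 in the
canonical layout). The profile coordinate of a fragment ending at `end3` is

$$\text{distance upstream} = \text{stall\_start} - \text{end3},$$

positive upstream of the stall. Ends at or downstream of the stall
(distance ≤ 0) are retained by `map_reads()` in a flagged bin but never
enter the upstream profile. `synthetic_reporter()` provides a random-sequence
reporter with this canonical geometry for examples and simulations; the
sequence is synthetic, only the coordinate layout is meaningful.

# Read mapping

* **Trimming** (`trim_adapter()`): the longest match wins, scanning adapter
  start positions 5′→3′; a full internal adapter, or a 3′-terminal read
  suffix matching an adapter prefix of at least `min_overlap` nt (default 6),
  qualifies when its mismatch count is at most
  `floor(max_mismatch_frac × aligned length)` (default fraction 0.1). Reads
  with no qualifying match are *rejected*, not errored: without the adapter
  the fragment's 3′ end is unknowable. The defaults are conventional
  adapter-trimming practice.
* **Alignment** (`align_fragment()`): ungapped minimum-Hamming placement over
  all forward-strand offsets, accepted iff the minimum distance is at most
  `max_align_mismatches` (default 2) *and* unique; trimmed fragments shorter
  than 15 nt are rejected up front. The forward-strand restriction follows
  from the library design (reporter-specific 5′ primer, 3′ adapter). The
  candidate search uses `Biostrings::matchPattern`; the test suite checks it
  against an independent all-offsets Hamming scan. Rejections are
  categorised (`too_short`, `too_many_mismatches`, `ambiguous`) and fate
  counts always partition the input reads — nothing is collapsed, and every
  read is one observation.

# Profiles, smoothing and peak labelling

`build_histogram()` bins upstream distances at 1-nt resolution over the
window 1..`upstream_window` (default 600 nt). Smoothing a per-read scatter
and smoothing this 1-nt histogram are equivalent, and the histogram is the
only track the package needs.

`smooth_profile()` applies Savitzky–Golay smoothing — at each position, the
value of the least-squares polynomial (default order 2) fitted over the
centred window (default 5 points). The coefficients come from
`signal::sgolay`; the unit-impulse centre response of the 5-point quadratic
is exactly 17/35. Positions within half a window of the edges carry `NA`
rather than an extrapolated value, so edge-fit artifacts cannot seed peaks
near the stall.

`call_peaks()` labels peaks in two steps:

1. **Candidates** are local maxima of the smoothed track: strictly greater
   than both neighbours, with a plateau (a run of equal values flanked by
   strictly smaller ones) reduced to its most-upstream position — one
   deterministic rule for integer-count ties. Candidates must additionally
   have *positive* smoothed height: counts are non-negative, and the
   quadratic kernel's negative side lobes (−3/35) otherwise promote the flat
   zero stretches between isolated count clusters into spurious
   "peaks" at height 0.
2. **Labelling**: the threshold is the `peak_quantile` (default 0.75)
   quantile of the smoothed values across the whole analysis window,
   computed with linear interpolation between order statistics
   (`stats::quantile` type 7, fixed so thresholds reproduce bit for bit); a
   candidate is labelled iff its height is at or above the threshold. The
   window-wide threshold matches the observation that only a small subset of
   the many visible bumps gets labelled in practice; the alternative —
   quantile over candidate peak heights only — is available as
   `threshold_on = "peaks"`.

`peak_spacing_stats()` summarises labelled peaks: consecutive spacings, the
modal spacing (rounded to the nearest nt, ties toward the smaller value),
the median spacing, and the span (max − min labelled distance). With fewer
than two labelled peaks the spacings are `NA` and the result is flagged
degenerate instead of erroring.

# Kinetics and growth

**Half-lives** (`fit_half_life()`): per replicate, ordinary least squares on
$(t, \ln A)$; $t_{1/2} = \ln 2 / |\hat\beta|$. The log-linear fit is exact
on noiseless exponential decay and is the standard quantification for
shutoff time courses; nonlinear exponential fitting would add nothing at
the 4–6 timepoints typical of these experiments. Replicates with a
non-negative slope are flagged non-decaying and excluded from the mean ± SD
summary with a warning; if all replicates are non-decaying the fit errors.
Multiplicative lognormal noise (unit mean, CV = `noise_cv`) is the
simulator's noise model because normalized blot signals are strictly
positive.

**Growth lag** (`instantaneous_rate()`, `lag_time()`): the OD series is
smoothed with a centred moving average (`smooth_k = 5` points, ~50 min at
10-min plate-reader sampling, without which read noise dominates raw central
differences), then differentiated by central differences. The maximal value
is the maximal instantaneous growth rate; the lag between two conditions is
the difference of their derivative-argmax times, positive when the test
condition lags. This argmax definition is the stated readout; threshold-
crossing lag definitions are out of scope. Tied maxima resolve to the
earliest time and are flagged, which keeps the lag antisymmetric.

**Polysome/monosome ratio** (`polysome_monosome_ratio()`): within each
user-supplied region of the A254 trace, the baseline is the trace minimum
inside the region (the valleys flanking the peak) and the height is the
maximum above that baseline; the statistic is the polysome/monosome height
ratio. Peak *height*, not area, is used deliberately.

# What the generators do and do not emulate

The synthetic models reproduce: boundary-positioned cleavage with the 15/30
footprint geometry and both queue regimes; adapter-bearing reads with
substitution errors and ligation failures; exponential decay with
replicate-level multiplicative noise; logistic growth with additive read
noise and condition-dependent lag. They do **not** model elongation dynamics
(no TASEP-style traffic), exonucleolytic trimming of fragment ends, ligation
or amplification sequence bias, indel sequencing errors, or diauxic/other
non-logistic growth phases. Tests passing on synthetic data therefore
demonstrate correctness of the analysis operations under the stated
generative assumptions, not robustness to every artifact of real libraries
— which is why the mapping stage reports categorized rejection fates rather
than silently absorbing unexpected reads.

# Numerical choices and problem sizes

* Quantile type 7 everywhere; Savitzky–Golay edge positions `NA`; strict
  local maxima with most-upstream plateau tie-break; positive-height
  candidate rule (rationales above).
* Seeds: every generator takes an explicit integer seed and restores the
  caller's RNG state; identical seeds give identical output.
* The validation suite exercises end-to-end periodicity recovery with 2000
  boundary events per footprint in {20, 30, 45} and a 4-deep queue
  (error-free reads, 600-nt window), 100 independent shutoff simulations at
  t½ = 4.7 min with 10% CV noise and 3 replicates, and 24-h growth curves at
  10-min sampling — sizes chosen to make the recovered statistics exact or
  stable at the stated tolerances while keeping the suite quick to run on a
  laptop.

# Known limitations

* The aligner is ungapped by design; indel sequencing errors shift a read
  into the `too_many_mismatches` or `ambiguous` fate rather than being
  rescued. Externally aligned SAM/BAM can be imported instead
  (`read_sam_fragments()`), where each record's rightmost aligned reference
  base is taken as the 3′ end.
* Whether observed 3′ ends are the exact endonucleolytic positions or have
  been nibbled before capture cannot be decided from the data the pipeline
  sees; the `jitter` parameter lets users explore the consequence without
  the package taking a position.
* Each input FASTQ is treated as one sample; pooling or splitting replicate
  libraries is left to the caller.
* Reading-frame phase analysis of cleavage sites and differential testing
  between genotypes are out of scope.
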