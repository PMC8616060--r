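---
title: "Methods: the four-state chromatin model and heterochromatin feature statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the four-state chromatin model and heterochromatin feature statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromstates)
```

## The model

chromstates segments a genome into chromatin states from the binding
patterns of chromatin proteins. Each protein track is reduced to a 0/1
call per fixed-width bin, and the vector of M calls per bin is modelled
by a hidden Markov model whose emission distribution, within a state,
is a product of independent Bernoulli distributions — one success
probability per track per state. This is the emission family used by
the widely adopted multi-track segmentation tools for binarized ChIP
data; it keeps the EM updates closed-form and makes the fitted emission
matrix directly readable as "how often is protein *m* present in state
*k*".

With K = 4 states the fitted model supports the band/interband biology
of polytene chromosomes: a promoter/interband state (**Aquamarine**,
defined by the highest emission of an interband marker such as CHRIZ),
a transcribed gene-body state (**Lazurite**, highest elongation-marker
emission among the remaining states), and two band states, of which the
most protein-depleted is **Ruby** (dense band/block material) and the
other **Malachite**. The labelling rule is deterministic given a fitted
model; exact marker ties are resolved toward the tied state with the
higher overall mean emission (the more protein-rich candidate takes the
more active label), and a tie between the final two states sends the
lower index to Ruby. K is a parameter; only the labelling step requires
K = 4.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `bin_size` | 200 bp | grid resolution; the convention of binarized-ChIP segmentation tools. Terminal bins are kept at their true (shorter) width so base-pair totals are conserved. |
| `quantile` | 0.9 | binarization threshold for continuous tracks: a bin is "on" when its value strictly exceeds the empirical 0.9 quantile (linear interpolation) of observed bins. Presence (peak-projected) tracks bypass this and use any-overlap. |
| `K` | 4 | number of hidden states. |
| `seed`, `n_restarts` | 17, 5 | EM restarts are seeded `seed + restart − 1`; the best converged log-likelihood wins, ties to the lowest restart index. |
| `tol`, `max_iter` | 1e-6, 500 | EM stops when the relative log-likelihood improvement drops below `tol`; a run hitting `max_iter` is returned flagged, not failed. |
| `eps` | 1e-6 | probability floor on emissions/transitions, preventing degenerate zero-probability lock-in. |
| `alpha` | 0.001 | two-sided significance threshold for enrichment calls. |
| `counting_rule` | `start_in` | a feature counts in the region holding its leftmost base, so a partition counts each feature exactly once. |

## Numerical choices

The forward–backward recursions run in scaled linear space (per-bin
normalization constants accumulate the log-likelihood), with the per-bin
emission products computed in log space and column-rescaled before
exponentiation; this is underflow-safe for sequences far longer than
any chromosome considered here. Viterbi runs fully in log space and
breaks ties toward the lowest state index, making decoding
deterministic. Masked bins — assembly gaps, bins unobserved in any
track — split each chromosome into independent segments: the chain
restarts from the initial distribution rather than imputing unobserved
stretches, because the assemblies in this domain contain true sequence
gaps. Initialization draws emissions uniformly from [0.1, 0.9] with
sticky transitions (0.9 self); EM's log-likelihood is non-decreasing,
which the tests assert directly.

## Statistics

Het-vs-eu protein comparisons use the two-sided Mann–Whitney rank-sum
test; pairwise state comparisons use the same rank-sum test because the
sampling units (bins of different states) are unpaired — a signed-rank
mode exists for explicitly paired inputs but is never a default. The
exact null distribution is enumerated for pooled samples of at most 16
without ties; otherwise the tie-corrected normal approximation with
continuity correction is used. No multiple-testing correction is
applied by default, matching the fixed p < 0.001 convention of the
analyses this package supports; a Bonferroni option exists. The effect
size reported is log2 of the ratio of means, undefined (and flagged)
when either mean is zero.

One documented limitation: the sampling unit for the rank tests is the
bin, and neighbouring bins are autocorrelated, so bin-level p-values
are anti-conservative. Every enrichment table records this in its
metadata.

## Region bookkeeping

Region lengths come from border coordinates: a named region spans from
one marker position up to, but not including, the next, so its length
is the plain coordinate difference and abutting regions share a border
without overlapping. The shipped chromosome-3 partition records the
published variability-zone borders 22,267,604 and 23,151,844, whose
difference is 884,240 bp = 0.88424 Mb. (The source literature describes
this zone as "approximately 0.844 Mb"; the arithmetic difference of its
own printed coordinates is 0.884 Mb, and the package reports the
arithmetic value.) Regions whose coordinates were never published ship
as explicit `unknown` placeholders rather than invented numbers.

Densities are stored at full precision; display rounding uses one
decimal below 15 features/Mb and the nearest integer above, matching
how such densities are conventionally printed (7.5, 14, 60, 95).

The eight-level RPKM classifier implements the published integer bin
edges (>1000, 101–1000, 51–100, 26–50, 11–25, 4–10, 1–3, 0). The
printed edges leave fractional values (e.g. 100.5) unassigned; the
classifier resolves them with a monotone half-open chain — a value
between two bins joins the upper bin, values below 1 join
ExtremelyLow/None — which reproduces every printed edge exactly and
keeps the classifier total and order-preserving over nonnegative reals.
This was a genuinely open corner: the alternative (assigning gaps to
the lowest category) breaks monotonicity, so it was rejected.

## The synthetic-data generator

The generator emulates three things about the real inputs: (i)
multi-track binary occupancy driven by a segmental 4-state process —
the default truth model uses sticky transitions (0.95 self) and
emission profiles following the qualitative state biology (promoter
marker 0.9 in Aquamarine, elongation marker 0.8 in Lazurite, everything
0.05 in Ruby, moderate levels plus a distinctive band marker 0.7 in
Malachite), with every state pair separated by ≥ 0.4 in some track;
(ii) region-structured point annotations with Poisson counts at a
per-region density; (iii) per-tissue RPKM vectors realizing prescribed
expression-category tallies over 29 tissues. All generators are pure
functions of their seed and restore the caller's RNG state.

The het/eu preset builds a two-compartment genome whose state fractions
are constructed, not sampled: per-state bin quotas (het Ruby 0.700, eu
Ruby 0.519; Aquamarine+Lazurite three times smaller in het than eu) are
laid out as shuffled fixed-length runs, so the target fractions hold
exactly by design and the decoded segmentation can be audited against
them. Sampling the fractions from the Markov chain instead would leave
them ±1–2% of target at these sequence lengths, which would conflate
construction error with decoding error.

What passing tests on these data do **not** show: robustness to
spatially varying coverage, copy-number-driven signal loss,
antibody-specific binarization artifacts, or correlated noise across
tracks — real ChIP inputs have all of these, the generator has none.
Synthetic results validate the algorithmic chain, not any biological
claim about a particular dataset.

## Problem sizes and verification

The test suite validates the dynamic-programming core against
brute-force enumeration (total likelihood summed over all K^T paths and
exhaustive path maximization for K ≤ 3, T ≤ 8, at 1e-9), the exact
Mann–Whitney path against full permutation enumeration, and the
interval/binning arithmetic against per-base-pair oracles. Parameter
recovery is checked on 50,000 bins of 6-track synthetic data (emissions
recovered within ±0.05, typically ±0.01; Viterbi accuracy ≥ 0.95 after
optimal state alignment), a size at which recovery error is dominated
by model fit rather than sampling noise while the whole suite stays
fast. The null calibration check uses 1000 replicates at n = 50 per
group.

## Known limitations

* Emissions are conditionally independent given the state; correlated
  binding (e.g. complexes assayed by multiple antibodies) is absorbed
  into the state definitions rather than modelled.
* Viterbi produces a single hard path; posterior-marginal uncertainty
  is not propagated into the segmentation.
* The rank tests treat bins as exchangeable (see above).
* No liftover: mixing coordinates from different assembly releases is
  the caller's responsibility, and unknown chromosomes fail loudly for
  exactly this reason (`skip_unknown` relaxes it).
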