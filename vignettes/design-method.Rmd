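---
title: "Designing artificial disordered sequences: model and method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing artificial disordered sequences: model and method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpdesign)
```

## The design problem

An artificial intrinsically disordered protein (IDP) sequence is useful only
if a disorder predictor agrees it is disordered — uniformly, and at a chosen
level. The package therefore frames design as constrained rejection
sampling: generate random material, score it, and keep only what satisfies
two statistics of the per-residue disorder profile $D_o \in [0,1]$:

* **accuracy** — the mean $\bar D_o$ must lie within $0.025$ of the
  requested target $D_t$;
* **smoothness** — the range $\Delta D_o = D_{o,\max} - D_{o,\min}$ must not
  exceed $0.15$, so no part of the chain dips toward order.

Targets span $D_t \in \{0.55, 0.60, \dots, 0.95\}$: 0.5 is the conventional
disorder threshold of energy-based predictors, and 1.0 their ceiling.

## The reference scorer and its contract

Every component consumes a scorer through a minimal contract: a
deterministic map from an amino-acid string to one score in $[0,1]$ per
residue. Any external predictor can be wrapped with `as_disorder_scorer()`;
scores are validated on every call.

The reference implementation (`disorder_model()`) follows the
pairwise-energy family of disorder predictors. For residue $i$,

$$e_i \;=\; \frac{1}{|N_i|}\sum_{j \in N_i} M[a_i, a_j],
\qquad N_i = \{\, j : 2 \le |i-j| \le 100 \,\},$$

where $M[a,b] = -s_a s_b$ and $s_a = 1.2 - \mathrm{TOPIDP}(a)$ is a strictly
positive order weight (W largest, P smallest). Lower $e_i$ means more
stabilizing contacts, hence more order. Energies become scores through a
monotone logistic map
$D_o(i) = \mathrm{logit}^{-1}\!\big((e_i - \mu)/\tau\big)$ and are smoothed
by a centred 21-residue mean. Because $M$ is a negated product of positive
marginals, replacing any residue by a more disorder-promoting one can only
raise every energy, so the mean score is monotone in per-residue
propensity — the property the designer exploits.

Two calibration constants matter and are recorded in the default model (and
in any scorer parameter file written by `write_scorer_params()`):

| parameter | default | units | role |
|---|---|---|---|
| `neighborhood_min/max` | 2 / 100 | residues | composition window of the long-disorder regime |
| `smoothing_window` | 21 | residues | centred mean; odd, ≥ 1 |
| `propensity_shift` | 1.2 | — | keeps all order weights positive |
| `transform_midpoint` $\mu$ | −1.60 | energy units | centres the working range |
| `transform_slope` $\tau$ | 0.25 | energy units | spread of the working range |

$\mu$ and $\tau$ were calibrated once, by simulation, so that the mean
scores of random sequences over the 18-letter building-block alphabet cover
the target grid: under the defaults, 7×-repeated random 10-mers have mean
scores centred near 0.67 with a spread that reaches both the 0.55 and the
0.95 family at workable acceptance rates. The scorer makes no claim of
agreement with any particular published predictor; it reproduces the
*behaviours* the design procedure relies on (window of 21, long-range
composition sensitivity, W most order-promoting, P most disorder-promoting).

Numerical conventions: neighbourhoods and smoothing windows are truncated at
the termini and renormalized by the actual count; a sequence too short to
have any neighbour at separation ≥ 2 falls back to the residue's diagonal
energy $M[a,a]$; all spans and positions are 1-based and inclusive, matching
R convention (the central copy of a 7×10-mer occupies positions 31–40).

## Building-block library

`build_block_library()` proposes 10-mers uniformly (with replacement) over
the 18-letter alphabet — W is excluded as the most order-promoting residue,
C because disulphides can stabilize tertiary structure — and evaluates each
block at the centre of a 7× tandem repeat, i.e. with three full blocks of
flanking context on each side, which clears both the smoothing window's
10-residue reach and terminal truncation. A block is filed iff

1. $\Delta D_o \le 0.15$ over the central copy, and
2. its mean lies within $0.025$ of the nearest grid value.

Rule 2 is a deliberate tightening beyond the range criterion alone: without
it a block with, say, $\bar D_o = 0.40$ would be filed into the 0.55 family
and poison it, since family membership is the only thing the assembler ever
sees. A mean exactly equidistant between two grid values files to the lower
one (deterministic tie-break). Families fill independently to 50 blocks;
accepted blocks arriving at a full family are discarded, duplicates within a
family are permitted, and a global proposal cap (default $10^6$) guarantees
termination even under a pathological scorer.

## Sequence assembly

For requested length $l$ and target $D_t$, with $l_r$ the next multiple of
10 and $i = l_r/10$:

1. draw one family block, shuffle its residues once, tandem-repeat it $i$
   times — in a periodic sequence every residue sees the same neighbourhood
   composition, so the profile starts nearly flat and accurate (the
   comparison harness `compare_init_strategies()` quantifies how much worse
   concatenating distinct blocks starts out);
2. $j = i - 1$ times: draw and shuffle another same-family block, insert it
   between positions $L/2$ and $L/2+1$, delete five residues from each end,
   re-score the **entire** sequence, and accept only under the dual rule.
   A failed candidate is thrown away and a fresh block drawn; after 200
   failures at one insertion the whole sequence is discarded and assembly
   restarts from step 1 (after 50 discards, an error — the deterministic
   analogue of a wall-clock timeout);
3. trim $l_r - l$ residues one at a time, each time removing the terminal
   residue whose score (read from the frozen profile of the accepted
   $l_r$-length sequence, not re-scored per removal) deviates more from
   $D_t$; ties trim the N-terminus.

The dual criterion is *guaranteed* at length $l_r$; after trimming at most
nine residues it is re-computed and logged (`final_mean`, `final_delta`) but
not re-enforced, matching the stated step order of the procedure. Insertion
shuffling exists to fight repetitiveness: repeated protein sequence means
repeated DNA, which recombines in vivo.

Reproducibility: batches derive per-design seeds from the master seed by a
counter scheme (`master + 10007·rank`, reduced modulo the integer range), so
designs are independent yet replayable; every design carries provenance
(initial and inserted post-shuffle blocks, per-insertion rejection counts,
discard count) from which `replay_design()` reconstructs the sequence with
no random numbers. Ranking in the output name follows generation order.
An optional flag appends a single W for A280 quantification of an expressed
construct; it is off by default because it is a post-design, wet-lab
convenience that breaks the no-W alphabet guarantee.

## Numerical choices

* Threshold comparisons are inclusive ($\le$) with an absolute tolerance of
  $10^{-12}$, so a statistic computed exactly at a boundary is not rejected
  for $10^{-17}$-scale binary rounding.
* `which.min` resolves nearest-family ties toward the lower target.
* Windowed smoothing by cumulative sums agrees with per-window
  recomputation to well below $10^{-12}$ at design lengths; the test suite
  asserts equality against a loop-based oracle.
* Degenerate inputs (empty sequences, non-amino-acid letters, lengths
  outside 50–200, request sizes outside 1–10, off-grid targets) are
  rejected with errors naming the violated bound before any computation.

## What the randomized harness does and does not show

The library generator and benchmark harness emulate the method's own study
conditions: uniform 18-letter composition, nine families of 50 blocks,
thresholds 0.15/0.025, a 200-rejection cap, 50-request benchmark means. The
test suite runs the full pipeline at these conditions with reduced replicate
counts (e.g. 27 gate-checked designs across the grid, 4 × 50 benchmark
requests at $D_t = 0.55$, 216 initialization starts per strategy) — sizes
chosen to make the asserted trends statistically stable while keeping a full
run in minutes. Passing these tests shows the implementation realizes the
specified sampling process under its reference scorer; it does **not** show
that sequences are disordered under any other predictor, express well, or
avoid degradation — those are experimental questions outside a scorer's
reach. Known behaviours of the method that the harness reproduces only as
trends, not magnitudes: acceptance is hardest for low-$D_t$ families, and
discards grow with assembly length.

## Limitations

* The reference scorer is a documented stand-in satisfying the scorer
  contract; absolute score values are calibration-dependent, so libraries
  built under different scorers are not interchangeable (library files
  record their scorer parameters for this reason).
* No compositional, charge, or hydropathy constraints are imposed — only
  length and the two profile statistics.
* The trimming step optimizes greedily against a frozen profile; re-scoring
  after each removal could in principle choose differently.
* Hydrodynamic predictions are empirical power laws; they characterize
  expectations, not measurements.
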