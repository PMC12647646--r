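---
title: "CLA-MRFO: model, parameters, and design notes"
author: "clamrfo maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CLA-MRFO: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clamrfo)
```

## The optimizer

CLA-MRFO is a population metaheuristic for minimization over a box
$[\mathrm{lb}, \mathrm{ub}]^D$ built on the three movement operators of Manta
Ray Foraging Optimization and augmented with chaotic control, Lévy flights,
an elite memory, periodic local refinement, and partial restarts. A
population of $N$ individuals (default 200) evolves for $T_{\max}$
iterations (default 5000); the iteration ratio $r_t = t / T_{\max}$ anneals
every schedule from exploration toward exploitation.

**Chaotic control.** Each individual carries its own trajectory of one of
three fully chaotic maps — circle
$z' = (z + 0.2 - \tfrac{0.5}{2\pi}\sin 2\pi z) \bmod 1$, logistic
$z' = 4z(1-z)$, tent $z' = 2\min(z, 1-z)$ — rescaled to a control value
$C_i = 0.1 + 0.8 z_i \in [0.1, 0.9]$. The map equations and the affine
rescale are our canonical choices; seeds avoid known fixed points and
absorbing orbits, and a numerically collapsed state ($z < 10^{-6}$ or
$z > 1 - 10^{-6}$) is reseeded from the run RNG so trajectories stay chaotic
indefinitely.

**Movement operators.** Ranking the population by fitness (index $i = 0$ is
the best), the top third are *elite* and draw cyclone foraging with
probability $p_i = P_{\mathrm{cyclone}}\,(1 - 0.5\,i/N)(1 + 0.3\,r_t)$,
clipped to $[0,1]$; everyone else (and elites whose draw fails) uses chain
foraging. The category base $P_{\mathrm{cyclone}}$ multiplies the rank/time
factor so that both the per-category table and the rank-dependent form
contribute. The moves are

* chain (per dimension, gated by a uniform draw below
  $CR = CR_0(1 - 0.3 r_t)$):
  $x' = x + (C_i + \alpha)(x_{\mathrm{best}} - x)$ with
  $\alpha = 2C_i\sqrt{|\log(C_i + 10^{-10})|}$;
* cyclone: $x' = x_{\mathrm{ref}} + (C_i + \beta)(x_{\mathrm{ref}} - x)$
  with $\beta = 2 e^{C_i(1 - r_t)}\sin(2\pi C_i)$, where
  $x_{\mathrm{ref}}$ is the incumbent best (80% of draws) or a memory
  sample (20%);
* somersault (whole population):
  $x' = x + S(r\,x_{\mathrm{ref}} - (1-r)x)$, $r \sim U[0,1]$,
  $S = S_0(1 - 0.3 r_t)$, temporarily multiplied by 1.5 while the
  stagnation counter exceeds half its window (the escalation size is our
  choice; it is exposed in the configuration).

Every move is accepted per individual only if it improves that individual's
fitness (greedy selection). Together with elitism this makes the best-so-far
error trace non-increasing — a property the test suite asserts on every run
it executes. Boundary handling is clamping.

**Category schedules.** $P_{\mathrm{cyclone}}$, $S_0$, the local-search
period $F_{\mathrm{local}}$ and the stagnation window $T_{\mathrm{restart}}$
are keyed by function category, with a deceptive-landscape override:

| parameter | unimodal | multimodal | hybrid | composition |
|---|---|---|---|---|
| $P_{\mathrm{cyclone}}$ | 0.85 | 0.65 (0.45\*) | 0.55 (0.35\*) | 0.45 (0.35\*) |
| $S_0$ | 1.2 | 2.0 (3.0\*) | 2.2 (2.8\*) | 2.5 (3.5\*) |
| $F_{\mathrm{local}}$ | 3 | 6 (3\*) | 7 (3\*) | 8 (3\*) |
| $T_{\mathrm{restart}}$ | 20 | 15 (8\*) | 12 (10\*) | 10 (6\*) |

The deceptive flag is supplied by the user or the benchmark factory; no
automatic landscape detection is attempted.

**Initialization.** A hybrid mix: stratified Latin hypercube samples with
within-stratum offsets from a Cranley–Patterson-shifted van der Corput
stream (a scrambled low-discrepancy source; the `lhs` package provides plain
LHS but not this offset structure, so the sampler is implemented here),
Lévy-centered points around the domain midpoint, and uniform samples. The
default proportions are (0.65, 0.225, 0.125) — midpoints of the intended
ranges — with composition landscapes pushed to the maximum Lévy share
(0.60, 0.35, 0.05). Counts are apportioned by the largest-remainder rule so
they always sum to $N$. The Lévy scale is 10% of the range: wide enough for
exploratory spread, rarely saturating the clamp. Lévy steps use Mantegna's
algorithm with stability index $\beta = 1.5$ (exactly Gaussian at
$\beta = 2$, where Mantegna's variance formula degenerates).

**Memory.** Three banks of five entries each (total capacity 15).
Short/long banks accept a candidate when space remains or when it improves
the bank's worst entry by at least 10% in the scale-safe form
$(f_{\mathrm{worst}} - f_{\mathrm{new}})/(|f_{\mathrm{worst}}| + 10^{-12})
\ge 0.10$ (a plain percentage is undefined at zero or negative fitness).
The diversity bank requires the candidate's minimum distance to stored
members to exceed half their minimum pairwise distance; on eviction the
worse member of the closest stored pair leaves, which preserves the distance
property. Short-term entries older than 50 iterations are evicted first.
Retrieval picks a bank with weights 70/20/10 (short/long/diversity) and an
entry by softmax over negative fitness rank. Because the 10% rule can
reject a new global best whose margin over the bank's worst entry is below
10%, the optimizer additionally refreshes the long-term bank's worst entry
whenever the global best improves past the bank — elite preservation is a
separate mechanism from the quality-gated insertions.

**Local refinement.** Every $F_{\mathrm{local}}$ iterations the incumbent is
refined. The finite-difference step decays as
$h = 0.01(\mathrm{ub} - \mathrm{lb})(1 - 0.7 r_t)$ and the number of
perturbed dimensions follows a phase schedule (30% of dimensions while
$r_t < 0.3$, 15% to $r_t < 0.7$, then 5%, with a minimum of one). On
unimodal/multimodal categories the search is gradient-guided: a forward-
difference gradient on a sampled dimension subset followed by a line search
over a doubling/halving step ladder $2^{6} h \dots 2^{-20} h$; a round that
fails to improve shrinks the finite-difference step by 16, because the
forward-difference bias otherwise floors the achievable residual at
$O(h^2)$ — with this shrink, repeated calls on convex quadratics reach
$10^{-6}$ of the starting fitness within 50 calls, which the suite checks.
At most six rounds run per call, so the evaluation budget per call is
bounded by $6(k + 27)$ with $k$ the sampled dimension count. Hybrid and
composition categories avoid gradients (deceptive landscapes) and instead
probe five random unit directions in a sampled subspace at $\pm h$, or apply
Gaussian perturbations at scales $\{h, 3h, 10h\}$ — minimal realizations of
subspace directional search and multi-scale perturbation. In binary mode
(feature selection) the discrete analog runs instead: single-bit flips of
the incumbent mask over a sampled dimension subset, swept greedily — the
forward difference of a binary landscape is the bit flip.

**Restarts.** A counter tracks iterations without improvement beyond
$10^{-12}$; when it reaches $T_{\mathrm{restart}}$, the worst 35% of the
population (midpoint of the intended 30–40% range) is reinitialized by one
of three strategies — memory sample plus Gaussian noise at the local-search
step scale, Lévy steps around the domain midpoint, or uniform redraw —
drawn with weights (0.4, 0.3, 0.3), shifted to (0.2, 0.4, 0.4) early in the
run ($r_t < 0.3$) or on deceptive landscapes. The best individual is never
replaced and the counter resets after a restart. A Shannon entropy of the
population (10 bins per dimension, averaged over dimensions) is computed as
a diagnostic and can optionally co-trigger restarts via a configurable
floor; the no-improvement counter is the primary trigger because it is the
only concretely specified mechanism.

## Benchmarks, baseline, statistics

The function factory builds $f(x) = \mathrm{base}(M(x - o)) + \mathrm{bias}$
with a seeded random orthogonal $M$ (QR of a Gaussian matrix) and a shift
drawn in $[-80, 80]^D$ inside the canonical $[-100, 100]^D$ domain. Bases:
sphere, bent cigar, Rastrigin, Rosenbrock (optimum moved to the origin),
Ackley, Griewank. Hybrid instances are weighted sums of three rotated bases
sharing one shift (normalized absolute Gaussian weights); composition
instances take the pointwise minimum of three independently shifted
components with additive offsets (0, 100, 200) and per-component scales, a
deceptive multi-basin construction whose optimum is exactly known. Both
keep $f(o) = \mathrm{bias}$ exactly with nonnegative error, which every
instance is tested for. Officially distributed shift/rotation files can be
substituted through a plain-text loader; nothing is downloaded.

The baseline MRFO implements the original operator forms (chain following
the previous individual, cyclone around the best or a random point with
$\beta = 2 e^{r_1 (T - t + 1)/T}\sin 2\pi r_1$, somersault with fixed
$S = 2$) with unconditional position updates, tracking the best-so-far.

Comparison statistics: Friedman mean ranks and $\chi^2$ over a functions ×
algorithms error matrix (rank 1 = lowest error, average ranks on ties),
Nemenyi critical difference $q_\alpha\sqrt{k(k+1)/6n}$ with $q_\alpha$ from
the studentized range (`qtukey`), and a Wilcoxon signed-rank test with
$W = \min(W^+, W^-)$, exact two-sided $p$ by full $2^n$ enumeration for
$n \le 12$ and a tie-corrected normal approximation otherwise. The
enumeration is cross-checked in the tests against `stats::wilcox.test` where
both are exact.

## Feature selection

The wrapper encodes gene subsets as positions in $[0,1]^p$, binarized at
0.5 only at evaluation time (an all-zero mask switches on the single
largest coordinate), so the continuous search dynamics are unchanged;
memory distances are Hamming on the bits. Preprocessing: variance filter,
then a Welch $t$ screen keeping the top 100 genes by $|t|$. The objective
is the stratified 5-fold CV misclassification rate of the inner learner
plus $\lambda k / p$ ($\lambda = 0.01$); folds and learner randomness are
fixed by a seed so identical masks always score identically, and mask
evaluations are memoized within a run. The inner learner defaults to a
bagged tree ensemble (50 trees, depth about 5, via `randomForest`); a
linear SVM and a nearest-centroid classifier are available alternatives.
The nested protocol refits the whole pipeline (filter, screen, selector) on
each outer training fold only, evaluates the selected genes with the final
learner(s) on the held-out fold, and aggregates accuracy, weighted
precision/recall/F1, the summed confusion matrix, sensitivity/specificity,
and the mean subset size.

### What the synthetic generator emulates — and a caveat it exposes

The generator reproduces a two-class, high-dimensional, low-sample-size
design: 72 samples (47/25), standard log-scale Gaussian noise genes, and
$k$ informative genes shifted by a stated effect (in within-class SD units)
in class 2, optionally block-correlated or heavy-tailed. It does not model
probe-level artifacts, batch effects, or multi-class structure, so passing
tests demonstrate selector behavior under idealized signal, not robustness
to real microarray noise.

Working at effect size 2.0 exposed a structural property of wrapper
selection worth recording. With $n = 72$ and 5-fold CV, one misclassified
sample moves the objective by roughly $1.3\times 10^{-2}$, while the
per-feature compactness penalty is $\lambda/p = 10^{-4}$ — two orders
smaller. Compactness therefore only decides ties; whenever chance
correlations let a larger mask score even one CV misclassification fewer,
the larger mask wins. On this generator at effect 2.0 that is exactly what
happens with the tree-ensemble inner learner: dense masks CV-score better
than the true informative subset even though they generalize worse on fresh
data from the same distribution. Raising $\lambda$ enough to force
five-gene subsets collapses selection to one or two genes instead. At
effect 3.0 the picture inverts: a handful of informative genes reaches CV
error zero, no mask can score better, and the penalty then drives
ultra-compact subsets — the regime strong real signatures live in. The
recovery study in the test suite consequently runs the selector with the
nearest-centroid inner objective (whose error decreases with each
informative gene added and which does not reward noise ensembles) at a
reduced budget ($N = 60$, 60 iterations, five seeds); the tree-ensemble
default is retained for analysis use, and the weak-effect expectations
that remain unmet under these conditions are reported as failures rather
than relaxed.

## Problem sizes used by the test and acceptance runs

Chosen so the full suite completes comfortably on one core: unimodal
convergence studies use the $D = 10$ shifted-rotated bent cigar with
$N = 200$ (30 early-stopped runs for the success-rate study; 10 runs of
2000 iterations for the precision study); the baseline contrast uses
$N = 100$ and an 800-iteration budget over a sphere/bent-cigar pair;
stress properties use populations of 12–40 over 15–250 iterations; the
memory contract replays $10^5$ randomized insertions; the selection study
uses the generator defaults with the reduced selector budget above.

## Known limitations

* Pure-R execution: large populations in very high dimension pay R-level
  overhead; the design favors vectorized batch evaluation to compensate.
* The composition construction (pointwise minimum) is deliberately simple;
  it exercises deceptive-landscape code paths but is not the official
  benchmark-suite composition operator.
* The peer-algorithm interface accepts any optimizer with the run-record
  contract, but only CLA-MRFO and baseline MRFO ship in the package.
* Wrapper selection inherits CV-noise exploitation (above); on weak-signal
  data, subset compactness claims should be validated on held-out data.
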