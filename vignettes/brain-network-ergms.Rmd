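---
title: "Modeling whole-brain functional networks with ERGMs"
author: "brainERGM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling whole-brain functional networks with ERGMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainERGM)
```

## The model

A subject's whole-brain functional network is an unweighted, undirected
simple graph on n labeled nodes (anatomical regions of interest; n = 90 for
a standard atlas parcellation). An exponential random graph model (ERGM)
places a probability mass function on the space of all such graphs,

$$P_\theta(Y = y) = \frac{\exp\{\theta^\top g(y)\}}{\kappa(\theta)},$$

where $g(y)$ is a vector of sufficient statistics — local features such as
the edge count or weighted shared-partner sums — $\theta$ the parameter
vector, and $\kappa(\theta) = \sum_y \exp\{\theta^\top g(y)\}$ the
normalizing constant over all $2^{\binom{n}{2}}$ graphs. Each $\theta_k$ is
the change in the conditional log odds of an edge per unit change of the
corresponding statistic: positive values mean the feature is more prevalent
than under the Erdős–Rényi null model, negative values less. With only an
edges term the model *is* Erdős–Rényi with edge probability
$\mathrm{logit}^{-1}(\theta_{\text{edges}})$.

### Supported statistics

The package implements the statistics that are standard for brain networks
and mutually compatible in one model: `edges`, `two_path` (paths of length
two, $\sum_v \binom{d_v}{2}$), the geometrically weighted degree (`gwd`),
the geometrically weighted edgewise / non-edgewise / dyadwise shared-partner
sums (`gwesp`, `gwnsp`, `gwdsp`), and `nodematch` (edges joining nodes with
equal values of a categorical attribute such as lobe membership). The
geometric weighting uses the curved-ERGM convention

$$u(\mathbf{c};\tau) = e^\tau \sum_{k \ge 1}
  \left[1 - (1 - e^{-\tau})^k\right] c_k,$$

where $c_k$ counts entities (edges, non-edges, dyads, or nodes) with exactly
$k$ shared partners (or degree $k$). Increments at higher $k$ get
geometrically smaller weight, which is what protects these terms from the
classic ERGM degeneracy in which probability mass collapses onto near-empty
or near-complete graphs. The decay parameters $\tau$ are fixed and known,
not estimated; the package default is $\tau = 0.75$ for every weighted term
(configurable per term). Raw k-cycle and k-degree counts are deliberately
not offered: they are redundant with the weighted terms and are the classic
degeneracy culprits.

`bestAssessmentModel()` returns the edges + GWESP + GWNSP preset — one
connectedness, one local-efficiency and one global-efficiency term — the
combination that recurs across per-subject graphical selections of
whole-brain networks.

## Network construction

`thresholdByS()` turns a (partial) correlation matrix into a binary network
by the size-matching rule: with exponent $s$, the target mean degree is
$K = n^{1/s}$ (from $n = K^s$, the path-length relation of a random graph),
and exactly $E = \mathrm{round}(nK/2)$ edges are kept — the $E$ largest
off-diagonal entries. This makes networks comparable across subjects: same
n, same E. Defaults: $s = 2.5$ (K ≈ 6.05 at n = 90, matching mean nodal
degrees reported for resting-state networks built this way) and signed
(not absolute) ranking, since functional-connectivity thresholding in this
literature retains positive couplings; `absolute = TRUE` switches. Ties are
broken deterministically by (row, column) order, so construction is
reproducible.

## Estimation

Three routes, sharing one change-statistic engine (compiled, incremental,
cross-checked in the tests against a naive whole-graph recomputation):

* **`exactMLE`** enumerates all graphs for $n \le 7$ (Gray-code order, so
  each graph is one dyad toggle from its predecessor) and maximizes the
  exact likelihood; at the optimum the expected statistics equal the
  observed ones (exponential-family moment match), which is verified to
  $10^{-6}$ and reported. It exists for oracle checks, not for brain-scale
  data.
* **`mple`** is the maximum pseudo-likelihood estimate: logistic regression
  of the dyad indicators on the change statistics over all
  $\binom{n}{2}$ dyads. Exact for dyad-independent models, fast always, and
  the standard initializer for the Monte Carlo route. Its standard errors
  understate uncertainty under dyad dependence, which is why it is not the
  default inferential route.
* **`mcmcMLE`** is the Geyer–Thompson Monte Carlo MLE: starting at the
  MPLE, each iteration simulates `sampleSize` networks at the current
  $\theta$, maximizes the importance-sampling approximation of the
  likelihood ratio, and repeats. Defaults: 1000 networks per iteration,
  burn-in $10\binom{n}{2}$ toggles, thinning $\binom{n}{2}$, at most 20
  iterations, tolerance $10^{-3}$.

Three numerical choices in `mcmcMLE` deserve a note:

* **Partial stepping.** When the observed statistics lie outside the convex
  hull of the simulated ones (routine in the first iterations for strongly
  clustered networks), the unconstrained update diverges. The update
  therefore targets a pseudo-observation pulled inside the hull
  (coordinate-wise, 5% margin), plus a trust-region cap of 2 natural-
  parameter units per step. A full (unshrunken) step is required before
  convergence can be declared.
* **Convergence vs Monte Carlo noise.** The parameter change between
  iterations cannot fall below the Monte Carlo noise of the update itself,
  which is of order $\sqrt{\mathrm{diag}(I^{-1})/m}$. Convergence is
  declared when a full step is within $\max(\text{tol}, 2\,\text{mcse})$,
  and a final scoring step on a fresh sample averages away part of the
  remaining noise. Verifying agreement with the enumeration oracle to 0.05
  on six-node graphs needs the noise well below that bound, so those
  checks use $m = 10^4$ (where a fit takes well under a second); the
  default $m = 1000$ is sized for 90-node networks, whose standard errors
  are an order of magnitude smaller.
* **Degeneracy screen.** If an observed statistic *equals* an extreme of
  the simulated statistics — or a simulated statistic collapses to a
  constant that misses the observed value — for two consecutive
  iterations, the fit aborts with a degeneracy diagnostic rather than
  wandering.

The log-likelihood is reported on the absolute scale by bridge sampling
along the straight path from $\theta = 0$, where
$\log\kappa = \binom{n}{2}\log 2$ is known (8 steps of 125 simulated
networks by default). That makes AIC values comparable across models, which
the AIC selection procedure requires. Standard errors come from the inverse
of the estimated Fisher information $\widehat{\mathrm{Cov}}_\theta[g]$;
Wald p-values use the asymptotic Gaussian reference.

## Simulation

`simulateNetworks()` runs a Metropolis chain over dyad toggles: propose a
uniformly random dyad, accept with probability
$\min(1, e^{\pm\theta^\top\delta})$. The proposal is deliberately the plain
uniform one — correct and simple; a tie-no-toggle proposal would mix faster
on sparse graphs and is noted as an extension. Fixed seeds give identical
draws. Degenerate parameter vectors are not an error; nearly empty or
nearly complete draws trigger a warning instead, since the sampler is also
the tool one uses to *diagnose* degeneracy. Goodness-of-fit simulation
initializes chains at independent edges with the observed density;
de novo simulation starts from the empty graph.

## Goodness of fit and model selection

`gofSimulate()` compares the observed network with networks simulated from
the fitted model on four distribution families: degree, edgewise shared
partners, minimum geodesic distance (unreachable dyads kept as their own
category, never folded into a numeric bin), and the undirected triad census.
`plotGof()` draws the standard panels — logit of relative frequency,
simulated boxplots, observed solid line.

The visual comparison is quantified by `gofScore()`: per family and bin,
the absolute difference between the observed logit relative frequency and
the median over simulations, with smoothing
$p = (\text{count} + 0.5)/(\text{total} + 1)$ so empty bins are finite;
bins average within family, families average with equal weight. Equal
weighting is our choice where the field leaves the weighting open; the
score is a device for ranking candidate models, not an absolute measure.

Three selection procedures share one candidate lattice (every subset of the
candidate terms, edges always forced in — dropping it leaves the density
unidentified, and exhaustive search over $2^{p-1}$ subsets is affordable
for the seven candidate terms that matter here):

* `backwardPValueSelect`: drop the least significant term while any Wald
  p-value exceeds $\alpha = 0.05$ (our default; the procedure is standard
  but the level is a choice).
* `aicSelect`: minimum AIC over the lattice, on the absolute log-likelihood
  scale; failed fits enter as $+\infty$.
* `graphicalSelect`: minimum GOF score over the lattice, with every report
  retained.

`selectionHarness()` runs all three side by side, because they genuinely
disagree on realistic data — that disagreement is a finding, not a bug, and
the harness makes it visible. The test suite exhibits it on a planted
48-node dataset.

## Group comparison and representative networks

With one shared model per cohort, `compareTerm()` performs a Welch
two-sample t-test (Satterthwaite degrees of freedom) on the per-subject
estimates of one term, treating the estimates as data. The estimates' own
standard errors are *not* propagated into the between-subject variance —
a deliberate simplification matching how parameter profiles are compared in
this literature, and a known limitation: with few subjects and large
estimation error the test is conservative about the wrong thing.
`averageProfile()` returns the elementwise mean profile, from which
`simulateNetworks()` draws representative group networks.

`descriptiveMetrics()` reports the neuroimaging summary metrics (clustering
coefficient, characteristic path length, local and global efficiency, mean
nodal degree). The characteristic path length averages over reachable pairs
only — the convention of the small-world literature — with the number of
unreachable pairs reported alongside rather than hidden.

## Synthetic data: what it emulates and what it does not

The package generates every input it needs:

* `sharedPartnerExample()` is a six-node, seven-edge network whose dyads
  populate the 0-, 1- and 2-shared-partner bins of the ESP/NSP/DSP
  distributions. It is a reconstruction for documentation and testing: its
  distributions are computed from the graph, never transcribed, so the
  identities (DSP = ESP + NSP elementwise, $\sum \text{DSP} =
  \binom{6}{2}$, $\sum_k k\,\text{ESP}_k \equiv 0 \pmod 3$) hold by
  construction.
* `generateCohort()` draws per-subject parameters
  $\theta_s = \theta + N(0, \text{sd})$ and simulates one network per
  subject. The default conditions emulate a resting-state cohort: 10
  subjects, 90 nodes, the edges + GWESP + GWNSP model with
  $\theta = (-2.8, 0.6, -0.1)$ — the sign pattern of fitted whole-brain
  networks (sparse, clustered, with shared partners between non-adjacent
  regions rarer than chance) — calibrated once, by simulation at these
  settings, to give mean degree about 5 at n = 90. Between-subject
  standard deviations default to $(0.15, 0.04, 0.02)$: the GWESP term sits
  close to the phase boundary beyond which the model's mass shifts to
  dense graphs, so the spreads are sized to keep subjects in the sparse
  small-world regime the cohort emulates. (Real cohorts show larger
  spreads of the *estimates*, but much of that is estimation noise, and
  real profiles co-vary across terms; independent Gaussian noise of that
  size would routinely tip subjects across the boundary.) The sampler's
  stationary distribution near that boundary is bimodal, so an occasional
  subject still lands in the dense mode; `generateCohort()` flags such
  subjects (density outside $[0.01, 0.25]$) as degenerate rather than
  hiding them, because this bistability is a real and well-known property
  of shared-partner ERGMs.
* `generateCorrMatrices()` builds block-structured correlation matrices
  (modules with higher within- than between-module correlation, plus
  symmetric noise, unit diagonal, clipped to $[-1, 1]$), emulating the
  *output* of fMRI preprocessing. Thresholding them yields clustered,
  small-world-like networks.

What the synthetic data does **not** emulate: fMRI time series, motion and
physiological artifacts, the estimation noise of partial correlations,
spatial embedding (distance-dependent connection probability), and
inter-regional heterogeneity of degree. Passing tests therefore show that
the machinery is correct and calibrated under the stated generative
conditions; they do not show that any particular model is adequate for a
given real dataset — that is what the GOF machinery is for on the data at
hand.

## Problem sizes used by the checks

The shipped checks run at the scales the methods are designed for while
staying desk-sized: enumeration oracles at n ≤ 7; estimator agreement on
six-node graphs; sampler calibration at n = 50 with 500 draws; parameter
recovery and GOF self-consistency at n = 90 (10 and 1 networks
respectively, 100 GOF simulations); the selection harness on one planted
48-node dataset; and null calibration of the cohort comparison with 500
replicates of 5-vs-5 cohorts at n = 30 fitted by MPLE (the null behavior
of the t-test does not depend on the fitting route, and the pseudo-
likelihood estimates are unbiased enough under these mild conditions).

## Known limitations

* Undirected, unweighted graphs only; directed/weighted extensions are out
  of scope.
* $\tau$ is fixed, not estimated (no curved-family optimization).
* The uniform-dyad proposal mixes slowly on very sparse, very large
  graphs; fitting has been exercised up to n = 90.
* Bridge estimates of the log-likelihood carry Monte Carlo error (fractions
  of a unit with the defaults); AIC differences smaller than that are not
  meaningful.
* F-tests across more than two groups are not implemented; only pairwise
  t-tests.
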