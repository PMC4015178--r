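---
title: "Testing lumpability of nucleotide recoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing lumpability of nucleotide recoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumpability)
```

## The pairwise SRH model

Two homologous sequences A and B of length $n$ are assumed to have diverged
from a common ancestor under **stationary, reversible, homogeneous** (SRH)
Markovian evolution, with sites independent and identically distributed.
Their data reduce to the divergence matrix $N = \{n_{ij}\}$, the count of
sites in state $i$ in A and $j$ in B, which is multinomial with cell
probabilities $F(t) = \{f_{ij}(t)\}$.

Reversibility factorizes the rate matrix as $R = S\Pi$ with
$\Pi = \mathrm{diag}(\pi)$ and $S$ symmetric. Throughout the package the
state order is **A, C, G, T** and the six free entries of $S$ are stored as
$s = (s_{AC}, s_{AG}, s_{AT}, s_{CG}, s_{CT}, s_{GT})$. With the symmetric
eigendecomposition $\Pi^{1/2} S \Pi^{1/2} = L \Lambda L^T$,

$$P(t) = \Pi^{-1/2} L e^{\Lambda t} L^T \Pi^{1/2}, \qquad
  F(t) = \Pi^{1/2} L e^{2\Lambda t} L^T \Pi^{1/2} = P(t)^T \Pi P(t),$$

so $F$ is symmetric with margins $\pi$. Time is fixed at $t = 1$ for
estimation and testing: rescaling $t$ is equivalent to rescaling $s$, so the
divergence time is not separately identifiable from pairwise data and $s$
absorbs the total path length. `simulateAlignment()` exposes real edge
lengths for multi-taxon simulation; the two-taxon convention is one time
unit per lineage.

The model has nine free parameters (3 in $\pi$, 6 in $s$), exactly the
dimension of a symmetric 4×4 probability matrix, so the maximum-likelihood
fit is closed-form (`estimateSRH()`): symmetrize
$\hat F = (N + N^T)/2n$, read $\hat\pi$ off its row sums, and recover
$\hat\Lambda$ as half the log of the eigenvalues of
$\hat\Pi^{-1/2}\hat F\hat\Pi^{-1/2}$.

Degenerate inputs are handled explicitly. A state absent from both
sequences makes $\hat\pi$ hit the boundary and raises an error. A
non-positive eigenvalue of the symmetrized matrix means the sequence pair is
saturated for this model; the default is an error suggesting longer
sequences, with an opt-in `clamp = TRUE` that clips eigenvalues at
$10^{-10}$. Noisy data can legitimately produce slightly negative fitted
exchangeabilities; estimates are returned as computed, and the `model` slot
of the fit is `NULL` when they do not form a valid generating model.

## Recoding and lumpability

A recoding scheme is a partition of $\{A, C, G, T\}$ into $q \in \{2, 3\}$
blocks; there are exactly 13 (six merging one pair, four merging a triplet,
three merging two pairs), catalogued by `listSchemes()` under their IUPAC
names. The recoded process is Markovian for every starting distribution —
the original process is *strongly lumpable* — exactly when block-row sums of
$P(t)$ (equivalently of $R$) are constant within each block, i.e.
$VUP(t)V = P(t)V$ for the membership matrix $V$ and the collapse operator
$U = (V^T\Pi V)^{-1} V^T \Pi$.

Two equivalent characterizations drive the package:

* the **defect** $M = VUP(t)V - P(t)V$ and its norm
  $\eta = (\sum_{ij} m_{ij}^2)^{1/2}$, zero iff lumpable
  (`lumpabilityDefect()`);
* two **linear constraints** $C(\pi)s = 0$ (`lumpabilityConstraints()`),
  derived mechanically from the rate-level criterion: within each block of
  size $\ge 2$, the $\pi$-weighted rate sums into every other block must
  agree across the block's states. Every scheme yields exactly two
  independent rows — this is why both $\chi^2$ reference distributions in
  the tests have 2 degrees of freedom. For one-pair and triplet merges the
  rows reduce to $\pi$-free equalities between exchangeabilities; for
  two-pair merges ($RY$, $SW$, $KM$) the coefficients involve $\pi$.

Deriving the constraints from the criterion, rather than hard-coding a
table per scheme, keeps the two routes independent: the test suite checks
$\eta \le 10^{-10} \iff C(\pi)s = 0$ over random draws for all 13 schemes,
and checks $\eta$ at $t \in \{0.5, 1, 2\}$ (lumpability is a property of the
generator, not of the evaluation time; the optional `multi.t` check guards
against a numerically accidental single-$t$ cancellation).

The projection $\tilde s$ of an estimate onto the lumpable subspace
(`projectToLumpable()`) is the Euclidean least-squares projection onto
$\{s : C(\hat\pi)s = 0\}$. When clipping at zero is needed, the
non-negative projection is computed by Dykstra's alternating projections
between the constraint subspace and the non-negative orthant, which
converges to the exact constrained least-squares solution for this pair of
convex sets. For one-pair and triplet merges the projection provably equals
the natural averaging rules (tied entries replaced by their mean), which is
kept as a regression test; for the $\pi$-dependent two-pair schemes a
closed form is not attempted.

The **joint distribution of the recoded pair** is $F_q(t) = V^T F(t) V$ (an
aggregation of a joint distribution must itself be the joint distribution of
the blocks), $\Pi_q = V^T \Pi V$, and the $q$-state reconstruction
$P_q(t)$ follows by the same spectral route. The conditional matrix
$P'(t) = U P(t) V$ is always a stochastic matrix; $P_q = P'$ exactly when
the process is lumpable, and the gap between them is what biases analyses
of non-lumpably recoded data. The scale factor

$$\rho = \frac{-\sum_i \pi_i r_{ii}}{-\sum_k \pi_{q,k} r_{q,kk}}$$

is oriented as original rate over lumped rate, so that recoded distances
equal original distances divided by $\rho \ge 1$: recoding hides
within-block substitutions and can only shorten edges. For Jukes–Cantor
parameters and RY this is $\frac{3/4}{1/2} = 1.5$ in closed form.

## The three tests

**Index test** (`indexTest()`). $\hat\eta$ is computed from the
unconstrained fit; its null distribution is approximated by a parametric
bootstrap: project the fit to $(\hat\pi, \tilde s)$, build
$\tilde F(1)$, draw $B$ matrices $N^*_b \sim$ Multinomial$(n, \tilde F(1))$,
re-estimate, and recompute $\eta^*_b$. The p-value is the plain proportion
$\#\{\eta^*_b \ge \hat\eta\}/B$; an add-one variant
$(1 + \#)/(B + 1)$ is available by flag when a strictly positive p-value is
needed. Default $B = 500$; the test suite uses $B = 200$, which leaves the
5%-level calibration inside the binomial tolerance. Bootstrap replicates
whose re-estimation fails (saturation) are resampled up to five times, then
counted and reported; the test aborts if more than 10% of replicates fail.

**Markov-chain test** (`markovChainTest()`). Sequence A is taken as
ancestral, so under SRH the divergence matrix has the properties of a
transition count matrix, and the observed block-aggregated counts
$o_{il} = \sum_{j \in S_l} n_{ij}$ are compared with
$e_{il} = n_{i\cdot} n'_{kl} / n'_{k\cdot}$. $T = \sum (o-e)^2/e$ is
referred to $\chi^2$ with $(q-1)\sum_k(\gamma_k - 1) = 2$ df. A zero
expected cell is an error naming the offending cell; `swap = TRUE`
transposes N for sensitivity analysis; no symmetrization is applied.

**Likelihood-ratio test** (`likelihoodRatioTest()`). The constrained
maximum under $H_0$ is found by alternating optimization
(`constrainedMLE()`): rotate $s$ by an orthogonal basis $A$ whose first two
rows span the rows of $C(\pi)$ (built by Gram–Schmidt, completed from
coordinate vectors in a fixed order, so $A$ is reproducible), pin the two
constraint coordinates of $y = As$ at zero, and maximize over the four free
coordinates given $\pi$ (BFGS on the spectral likelihood, with a smooth
quadratic penalty keeping $s \ge 0$); then maximize over $\pi$ on the
softmax-parameterized simplex given $s$; repeat until the log-likelihood
gains fall below `tol` ($10^{-8}$ by default). For two-pair schemes $C$
depends on $\pi$, so $A$ is rebuilt after every $\pi$ update and the
constraints are re-imposed exactly once more after convergence. The starting
point is the Euclidean projection of the unconstrained fit, so the
constrained optimum can only improve on it. $2LR$ is referred to
$\chi^2_2$; values in $[-10^{-6}, 0)$ — numerical noise, since the
unconstrained maximum is closed-form — are clamped to zero, anything more
negative is an optimization-failure error. Whether non-negativity of $s$
should bind during the rotated updates is not determined by theory alone;
this implementation enforces it, since a negative exchangeability is not a
substitution model.

The independent cross-check for the constrained optimum is deliberately not
the $A$-matrix machinery: for a $\pi$-free scheme the null can be
parameterized directly by tying the constrained exchangeabilities, and a
generic multi-start optimizer over those seven parameters reproduces the
alternating optimum to $10^{-4}$ log-units in the test suite.

`bowkerTest()` (matched-pairs test of symmetry) is included as an SRH
screen: the lumpability tests presuppose SRH, and a PP-plot of symmetry
p-values across pairs is the practical check of that premise. Pairs with
$n_{ij} + n_{ji} = 0$ are dropped from both the statistic and the degrees
of freedom.

## Simulation machinery and what it does (not) emulate

`sampleDivergenceMatrix()` draws $N \sim$ Multinomial$(n, F(1))$ — the exact
sampling distribution of the two-taxon model. `simulateAlignment()` draws
root states from $\pi$ and propagates each site independently down a tree
with $P(\text{edge length})$ per edge. The generator therefore emulates
exactly what the model assumes: global SRH, site-i.i.d. evolution, no
indels, no rate heterogeneity across sites, no compositional drift between
lineages. Passing calibration tests on these data shows the tests are
correct *under the model*; it does not certify behaviour on real data that
violate SRH — which is why the SRH screen precedes the lumpability tests in
the intended workflow.

Experiment drivers reseed replicate $r$ with `seed + r`, so runs are
reproducible and can be partitioned; the index-test bootstrap inside a
replicate consumes that replicate's stream.

Default study conditions follow the two-taxon experimental setup used
throughout the package: $\pi = (0.1, 0.2, 0.3, 0.4)$ with
$s = (0.2, 0.25, 0.2, 0.2, 0.15, 0.2)$ (an RY-lumpable null), sequence
length $n = 1500$, and the alternative raising $s_{AC}$ to 0.5
($\eta \approx 0.058$, a mid-range departure). The test suite runs 1000
calibration replicates with $B = 200$ bootstraps and 300 power replicates —
sizes chosen so the binomial Monte-Carlo error is small relative to the
checked bands while the suite stays desk-scale; larger runs are a flag away
via `replicates` and `B`.

The shipped 7-leaf tree (`inst/extdata/sim_tree_synthetic.nwk`) is a
synthetic fixture with deliberately varied path lengths, used for
multi-taxon and recoding-bias experiments. Varied pairwise path lengths
matter for the bias demonstration: under a lumpable scheme the
original/recoded distance ratio equals $\rho$ for *every* pair regardless
of path length, while under a non-lumpable scheme the ratio drifts with
path length — which is precisely how `recodingBiasExperiment()`
distinguishes uniform rescaling from genuine distortion. Its exact mode
(`n.sites = NULL`) feeds expected counts $F(t_{\text{pair}})$ through the
same estimators, giving the infinite-data limit without sampling noise.

## Numerical conventions

* Eigendecompositions use the symmetric solver on symmetrized inputs;
  eigenvector signs are fixed by making each vector's largest-magnitude
  component positive (first such component on ties), so $L$ is reproducible
  across platforms.
* Structural tolerances: $10^{-10}$ for stochasticity/stationarity/detailed
  balance, $10^{-12}$ for symmetry and total mass, $10^{-8}$ for
  estimate-to-$\hat F$ round-trips, $10^{-10}$ as the $\eta$ threshold for
  "lumpable". They live in one place (`R/lumpability-package.R`).
* Transition probabilities are clipped at zero before multinomial sampling
  (spectral reconstruction can produce $-10^{-17}$-scale entries).

## Known limitations

* Pairwise only: the multi-taxon workflow tests all pairs under a *global*
  SRH assumption; p-values across pairs sharing lineages are dependent, so
  they are summarized by PP-plots rather than corrected for multiplicity.
* No rate heterogeneity across sites, no non-homogeneous or non-reversible
  processes, no indels.
* Nucleotides only: the operator algebra would carry over to amino-acid
  partitions (e.g. Dayhoff groups), but the catalogue, constraint
  derivation and tests here are specific to the 4-letter alphabet.
* Weak lumpability (Markovian only for particular starting distributions)
  is out of scope; the tests address strong lumpability.
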