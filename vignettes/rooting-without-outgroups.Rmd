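---
title: "Rooting phylogenies without outgroups: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rooting phylogenies without outgroups: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Almost all phylogenetic inference is done under time-reversible
substitution models, for which the likelihood of a tree is identical
wherever the root is placed (the *pulley principle*). The root must then be
supplied from outside the model, usually by including an outgroup — which
is not always available, and whose long connecting branch is itself a
well-known source of artifacts.

A *nonreversible* Markov model breaks this indifference. The fully general
("unrestricted") DNA model gives each of the 12 off-diagonal entries of the
rate matrix $Q$ its own parameter; because detailed balance
$\pi_i Q_{ij} = \pi_j Q_{ji}$ no longer holds, the likelihood of a rooted
tree depends on where the root is, and the root becomes an estimable
parameter. `rootphylo` implements this estimation on a fixed topology,
together with the statistics needed to say how much the data actually know
about the root:

* **ML root search** — every branch of the unrooted topology is tried as
  the root branch, with the root's position along the branch optimized;
* **rootstrap support** — the proportion of nonparametric bootstrap
  replicates whose root falls on each branch of the ML tree;
* **rBED / rSED** — branch-length and split distances between an inferred
  root and an assumed true root branch;
* **AU confidence set** — the set of root placements not rejected in favor
  of the ML placement by the approximately unbiased test;
* **ΔSLS / ΔGLS** — site- and locus-wise log-likelihood differences
  between two competing root hypotheses;
* **symmetry filtering** — matched-pairs tests that flag loci violating
  the stationarity/homogeneity assumptions the nonreversible model still
  makes.

## Model and likelihood

The engine is generic over the state-space size $K$; DNA ($K=4$, 12 free
rates) is the primary use. A model is assembled from its off-diagonal
rates; the stationary distribution $\pi$ is the null left vector of $Q$,
and $Q$ is rescaled so that $-\sum_i \pi_i Q_{ii} = 1$, i.e. branch lengths
are expected substitutions per site at stationarity. One rate is anchored
to 1 during fitting, since the overall rate is absorbed by this
normalization — 11 free rate ratios for DNA.

Likelihoods use Felsenstein pruning over compressed site patterns with
per-pattern rescaling (no underflow on long trees), implemented in C++.
Transition matrices $P(t) = e^{Qt}$ are computed by eigendecomposition with
a scaling-and-squaring (Padé) fallback when the eigenbasis is
ill-conditioned (condition number above $10^{12}$) — nonreversible $Q$ can
have complex or near-defective spectra. Gaps and ambiguity codes are
treated as fully missing (conditional likelihood 1 for every state), the
standard convention.

Root-state frequencies default to the stationary $\pi$ of the fitted $Q$;
`free_root_freqs = TRUE` estimates them separately (a softmax
parameterization with $K-1$ free logits). Stationarity at the root is the
common default, and nothing in the rooting method requires it.

## The root search

The search takes the topology and branch lengths as given (they would
typically come from a reversible, partitioned analysis) and:

1. fits the model once at an arbitrary rooting;
2. for each branch, reroots there, optimizes the root's *split fraction*
   $f \in [0,1]$ along the branch by bounded scalar search, and refits the
   model warm-started from the previous fit;
3. returns the branch with the highest optimized log-likelihood, after a
   final full-tolerance polish at that branch.

All branch lengths except the root branch are held fixed; the root branch
keeps its total length, split $f : 1-f$. Holding lengths fixed keeps the
search at desk scale and respects the workflow in which lengths come from a
reversible fit of the same data. Per-branch scan fits run at a coarser
optimizer tolerance than the final polish: the argmax over branches only
needs resolution well below the between-branch log-likelihood differences,
which are orders of magnitude larger than the scan tolerance whenever the
root is identifiable at all.

Ties within `tie_tol` ($10^{-6}$ log-units) set a flag and resolve to the
first branch in canonical bipartition order. A reversible model with
stationary root frequencies ties *every* branch — the package's tests use
this as a built-in sanity check in both directions (reversible models must
tie; sampled nonreversible models must not).

The optimizer is L-BFGS-B on log-transformed rates, bounds $\pm 15$ on the
log scale, convergence at an absolute objective change of about $10^{-6}$
for the default tolerance, at most 500 iterations, with up to 3 perturbed
restarts if the likelihood turns non-finite (which can happen when extreme
rate proposals make a pattern's likelihood underflow to zero).

## Rootstrap, and what it does and does not say

A nonparametric bootstrap resamples alignment columns with replacement
(implemented as a multinomial redraw of site-pattern weights, which is the
same thing), reruns the root search on the fixed topology for each
replicate — the model warm-started from the full-data fit and refit briefly
against the replicate weights, then the root position re-optimized on every
branch — and records each replicate's root branch. The rootstrap support of
a branch of the ML tree is the fraction of replicates whose root
bipartition equals that branch's bipartition; there is no partial credit
for nearby branches. Replicates rooted on a bipartition absent from the ML
tree accumulate in `unplaced_mass`, so supports sum to at most 1 (exactly 1
minus the unplaced mass, in rational arithmetic with denominator $B$).

Because matching is by bipartition, tip branches exist in every replicate,
while an internal branch's rootstrap can never exceed its classical
bootstrap occurrence frequency. Replicate $r$ draws its RNG substream from
the $r$-th element of `sample.int(.Machine$integer.max - 1, B)` under the
user's seed, making the whole analysis bit-reproducible.

The rootstrap measures *robustness* of the root placement under
resampling, not correctness. When the truth is known (simulation) or
assumed, rBED and rSED measure *accuracy*: rSED counts the internal nodes
strictly between the ML root branch and the true root branch (0 on the
same branch, 1 for adjacent branches), and rBED is the interval from the
nearest to the farthest point of the true root branch, measured from the
inferred root point along the tree. On the same branch rBED starts at 0
and ends at the distance to the branch's farther end — which can exceed
the rBED of a nearby *different* branch; that is why both metrics are
reported. When the assumed true branch does not exist in the ML topology
at all, both functions raise a branch-not-found error rather than guessing
a value.

## The AU confidence set

The AU test is run over one candidate per branch: the tree is rerooted on
each branch with the root position optimized under the *fixed* full-data
model (no per-candidate refit — the desk-scale choice; the optimized
fraction per branch is recorded in the result), giving a matrix of
per-site log-likelihoods. Multiscale RELL bootstrap then resamples site
columns at relative sizes $r \in \{0.5, 0.6, \ldots, 1.4\}$, $10^4$
replicates per scale by default, records the frequency with which each
candidate attains the maximum resampled total, and fits
$z(\sigma) = d/\sigma + c\,\sigma$ (with $\sigma = 1/\sqrt{r}$ and
$z = \Phi^{-1}(1-\mathrm{BP})$) by weighted least squares, the weights
coming from the binomial variance of each frequency. The AU p-value is
$1 - \Phi(d - c)$; the confidence set at level $\alpha$ keeps every
placement with $p \ge \alpha$ and always contains the ML placement, which
cannot be rejected in favor of itself. Degenerate inputs (all candidates
identical at every site) return $p = 1$ for everyone by convention;
frequencies of exactly 0 or 1 at every scale short-circuit to $p = 0$ or
$1$; a WLS failure yields `NaN` with a warning rather than a fabricated
p-value.

ΔSLS is the per-site log-likelihood difference between exactly two
candidate rootings, with sites counted as favoring one side, the other, or
neither (zero differences are "equal", not split); ΔGLS sums ΔSLS within
each locus of a partition map that must cover every site exactly once. The
loci with the largest $|\Delta\mathrm{GLS}|$ are the natural targets of
filtering experiments, so the result table is sorted by that magnitude.

## Symmetry filtering

Nonreversible models drop reversibility but keep stationarity and
homogeneity. For a stationary, homogeneous process the *expected* joint
substitution-pattern counts of any sequence pair are symmetric, so
asymmetry is evidence of violation. The matched-pairs statistic
$\sum_{i<j} (n_{ij}-n_{ji})^2/(n_{ij}+n_{ji})$ over pairs with
$n_{ij}+n_{ji}>0$ is referred to a chi-square with one degree of freedom
per contributing pair. Per locus, the filter applies the test to the
sequence pair with the largest p-distance — the pair with the most
accumulated substitutions, where violations are most visible; this
selection rule is a documented choice of this package, with an
`all_pairs` mode (minimum p-value, optional within-locus correction)
available as the alternative. No multiple-testing correction is applied
across loci by default: filtering is reported at the raw locus level, and
correction is a switch. Columns with a gap or ambiguity in either member
of the tested pair are excluded, and loci without a single resolved pair
are labeled `untestable` rather than passed or failed.

## Synthetic scenarios

`generate_scenario()` draws a rooted tree (successive random attachment of
tips to a uniformly chosen branch, or a balanced shape), i.i.d. exponential
branch lengths, a substitution model, and an alignment evolved from root
states drawn from the model's root frequencies, with the truth (root
bipartition, split fraction, rates, $\pi$) recorded for scoring. The
default scenario is 8 taxa, exponential branch lengths with mean 0.1
substitutions/site, and 100 loci of 500 sites; rates are sampled
log-uniformly over $[0.1, 10]$ — two orders of magnitude, giving a
pronounced nonreversible signal. The `nonrev_strength` knob interpolates
the rate vector linearly between an independently sampled detailed-balance
(GTR-style) matrix and the free draw, giving a controlled difficulty axis:
at 0 the emitted model satisfies detailed balance to numerical precision
and the root is unidentifiable by construction.

Locus subsampling draws one permutation of the loci per seed and takes
prefixes, so the subsamples at different fractions nest (the 0.1% set is
inside the 1% set, and so on) — the natural design for
information-content curves against, e.g., the number of
parsimony-informative sites.

What the generator emulates is the statistical structure the method
assumes: a single homogeneous nonreversible process, stationary root
frequencies, independent sites, no rate heterogeneity across sites or
loci, no alignment error, no compositional drift between lineages. Real
data violate several of these at once, which is exactly why the symmetry
filter and the ΔGLS diagnostics exist. Passing tests on synthetic data
therefore demonstrate correctness of the machinery and behavior of the
statistics under the model's own assumptions — not robustness to their
violation.

## Problem sizes and numerical choices

The test suite exercises the engine at the scales a single desk machine
handles comfortably: exhaustive-enumeration likelihood checks on all
15 four-taxon rooted topologies; a 20-seed root-recovery experiment on the
default 8-taxon scenario at 10,000 sites; a 200-replicate rootstrap on a
decisive-signal fixture (a balanced tree with a mid-branch root and a model
draw screened for genuine root signal under the generating model);
parameter recovery at 50,000 sites; and symmetry-filter operating
characteristics over 10 seeds of 20 loci of 2,000 sites.

The recovery experiment is worth an honest caveat: with the default
generator, a sampled "fully nonreversible" rate matrix is not guaranteed
to carry a *strong* root signal, and the root's position on its branch is
itself random — some draws put the true root essentially at a node, or on
a branch of negligible length. On such draws the maximum-likelihood
rooting can genuinely prefer a branch adjacent to the true one (the
generating model itself assigns the inferred rooting a higher likelihood
than the true rooting), and no search improvement can recover those
datasets. This is the behavior the root-error metrics exist to quantify,
and it is why the rootstrap fixture screens for decisive signal explicitly
rather than trusting the knob. The engine is
generic in $K$ but is exercised at DNA scale.

Numerical conventions worth knowing:

* branch lengths absent from a Newick default to 0 with a warning
  (topology-only bootstrap files remain usable for rootstrap and rSED,
  which need no lengths; rBED refuses such trees);
* split fractions 0 and 1 are legal and give a zero-length root
  half-branch;
* trees over different taxon sets are incomparable and raise errors in
  every metric operation — bipartition matching is undefined otherwise;
* rerooting restores all edge lengths exactly from the source tree's
  bipartition map, so patristic distances are preserved to machine
  precision rather than to serialization precision;
* the binomial clade test uses a null success probability of 0.33
  literally — the conventional quoted value — rather than 1/3.

## Known limitations

Topology search, among-site rate heterogeneity (+G/+R), partition-linked
models, and codon models are out of scope: the tool roots a *given*
topology. The AU computation fixes the model at the full-data fit across
candidate placements; with few sites and a strongly root-dependent model
this is an approximation. Bootstrap replicates refit the model briefly
from a warm start rather than from scratch — at replicate level this is a
speed/fidelity compromise documented here rather than hidden. The
marginal- and internal-symmetry decompositions of the matched-pairs test
(stationarity vs homogeneity separately) are not implemented; the filter
uses the overall test only.
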