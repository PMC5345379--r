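---
title: "Models and methods in morphoclade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in morphoclade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoclade)
```

morphoclade implements a complete analysis pipeline for discrete
morphological character matrices: character coding, Bayesian inference under
the Mk/Mkv model with gamma rate variation, posterior summaries and monophyly
hypothesis testing, and a parallel maximum-parsimony analysis with bootstrap
and Bremer support. This vignette records the models, the tunable parameters
and their defaults, the numerical choices, and the design decisions taken
where more than one reasonable option existed.

## The data model

A `character_matrix` holds taxa by characters, where every cell is a
*state-set*: a singleton for an ordinary observation, a larger set for a
polymorphic taxon, and the full set `{0..k-1}` for missing data (`?` and the
gap symbol are both read as missing; the NEXUS dialect is the
MrBayes-compatible "standard" subset). Cells are stored internally as integer
bitmasks, which makes Fitch set operations and likelihood leaf partials
direct. Character numbering is 1-based everywhere a user sees it, matching
how morphological character lists are published; excluded characters keep
their number and column but contribute exactly nothing to any analysis.

Each character records its state count `k`. By default `k` is the number of
states implied by the observed cells (the behaviour of "standard" data in
common Bayesian software); simulated or user-supplied metadata may declare a
larger `k` explicitly.

## Character coding

Quantitative characters (measurement ratios or angles, one mean value per
species) are binarized at the across-species median: values strictly above
the median become state 1, values at or below it state 0. The tie-at-median
rule is a deliberate choice — the procedure is then deterministic and splits
`n` distinct values into ⌈n/2⌉ zeros and ⌊n/2⌋ ones; a configuration
switch is unnecessary because flipping the tie rule only relabels states.
Missing measurements are excluded from the median rather than imputed.
Binarization depends only on ranks, so any strictly monotone transform of a
column leaves the coding unchanged (this is asserted in the test suite).

Qualitative characters observed several times per species are *majority
coded*: the modal state is used; an exact tie is retained as a polymorphic
state-set rather than resolved arbitrarily, since the downstream machinery
handles ambiguity natively. Majority coding can never introduce a state that
was not observed.

## The Mk/Mkv likelihood

Characters evolve under the k-state symmetric Markov model: all transitions
share one rate (unordered), or only adjacent states communicate (ordered
chains, for characters whose states form a linear series). Both rate
matrices are scaled so one unit of branch length is one expected change
under the uniform stationary distribution, which makes branch lengths
comparable across characters with different `k`. Transition probabilities
come from the symmetric eigendecomposition; the pruning pass is implemented
in C++ with per-node, per-character rescaling of partial likelihoods, so
deep or long trees do not underflow.

Rate variation across characters uses the discrete-gamma approximation with
`ncat = 4` equal-probability categories by default. Category representatives
are the conditional category means (computed in closed form from the
incomplete-gamma function, so the discretized rates have mean exactly 1);
category medians renormalized to mean 1 are available as an option.

Morphological matrices systematically omit invariant characters, so the
default likelihood is conditioned on variability (the "v" in Mkv): each
character's likelihood is divided by the probability that the character is
variable on the tree,

$$\ln L_c^{\mathrm{corr}} = \ln L_c - \ln\!\bigl(1 - \textstyle\sum_s
\Pr(\text{all taxa in state } s)\bigr),$$

with the constant-pattern mass computed per character-group under the same
gamma mixture. Conditioning is per character with that character's own `k`.
A character that is entirely missing has constant-pattern mass 1 and is
rejected with an error under conditioning, as is a tree with no positive
branch length. The suite verifies, by full enumeration, that the corrected
likelihoods of all variable patterns sum to one, and that pruning matches a
brute-force sum over internal-state assignments to 1e-9 for ordered and
unordered characters with and without gamma.

How Bayesian software internally treats *ordered* "standard" characters is
not always documented; the adjacent-transition chain under the shared
normalization is this package's explicit definition, not a claim of
equivalence with any particular program.

## Bayesian MCMC

One cold Metropolis–Hastings chain per run samples topology, branch lengths
and (optionally) the gamma shape. Priors are proper and weakly informative:
uniform over unrooted labeled topologies, i.i.d. exponential branch lengths
with mean 0.1 expected changes, and an exponential(mean 1) prior on the
shape. All are configurable; they are pragmatic stand-ins for the "default
priors" convention of the field's software, which the package does not try
to reproduce exactly.

Proposals, with default weights:

* **NNI** (0.5): a uniformly chosen nearest-neighbour interchange. The NNI
  neighbourhood of an unrooted binary tree has constant size `2(n-3)`, so
  the uniform proposal is exactly symmetric, and NNI alone connects tree
  space. Subtree-pruning moves were deliberately left out of the default
  mix: a *uniform* SPR proposal is also symmetric (the SPR neighbourhood
  size is constant too) but sampling it exactly uniformly is considerably
  more delicate, and a non-uniform SPR without its Hastings factor would
  silently bias the posterior. At the tree sizes this package targets
  (tens of taxa) NNI mixing is adequate; the prior-only validation below is
  the evidence.
* **Branch-length multiplier** (0.4): one branch scaled by
  `exp(λ(u - 1/2))`, Hastings ratio equal to the multiplier.
* **Shape multiplier** (0.1, only with gamma): the same move on α.

The starting topology is uniformly random (sequential random addition on a
uniformly chosen edge yields the uniform distribution), with prior-drawn
branch lengths. Chains are bit-reproducible given their seed.

Draws are taken at the start of every `sample_every`-cycle block — cycles
0, s, 2s, … — so a chain of `c·s` cycles yields exactly `c` draws and a
zero-cycle chain yields the start state. Burn-in removes the first
⌊fraction·n⌋ draws (default 0.25, i.e. the first 20 of every 80 thousand).

With the likelihood forced constant ("prior-only" mode) the sampled branch
lengths reproduce the exponential prior (Kolmogorov–Smirnov) and the three
4-taxon topologies are uniform — a direct test that the proposal/Hastings
machinery is correct. With branch lengths held fixed on 4 taxa the chain
reduces to a 3-state sampler whose exact posterior is computable by direct
likelihood evaluation; sampled frequencies match it.

Convergence across independent runs is monitored by the average standard
deviation of split frequencies (ASDSF): for every nontrivial bipartition
reaching `min_freq` (default 0.10) in at least one run, the standard
deviation of its frequency across runs, averaged over such splits. Values
below 0.01 are the conventional stopping signal. Replicate analyses are
compared by harmonic-mean log marginal likelihood, and the replicate with
the highest value is flagged for inference.

## Posterior summaries and hypothesis tests

The majority-rule consensus contains exactly the splits with pooled
post-burnin frequency *strictly* greater than 0.5 (such splits are pairwise
compatible and therefore form a tree); each is labeled with its frequency
and carries the mean branch length over supporting trees. Multiple runs are
pooled after per-run burn-in.

The posterior probability of monophyly of a taxon set is the fraction of
post-burnin trees in which the set forms a clade after rooting on the
designated outgroup; this equals the frequency of the corresponding
unrooted bipartition. "Wild" taxa are pruned from every sampled tree before
testing, so a rogue terminal does not veto an otherwise stable clade. A
clade never seen in `n` draws is reported as the upper bound `< 1/n` rather
than zero. The subtending branch length of a supported clade is converted
to expected character changes (posterior-mean per-character length times the
number of included characters) for the credibility correction.

Posterior probabilities on short branches — fewer than about 35 expected
changes — are known to overstate clade credibility for morphological data.
The package therefore applies a monotone lookup of the minimum PP deemed
95%-credible at a given branch length. The shipped default table is a
conservative synthetic stand-in (the historical table is not reproduced in
this package's sources): below 35 changes the threshold rises from 0.99
toward 1, and below 5 changes no PP qualifies; at or above 35 changes the
plain 0.95 rule applies. Users with the original published table should
supply it via the `table` argument, which accepts any nonincreasing lookup.

Model choice uses Bayes factors on the `2 ln` scale from harmonic-mean
marginal likelihoods (computed stably in log space). The verdict bands are
0–2 ("not worth more than a bare mention"), 2–6 ("positive"), 6–10
("substantial"), and above 10 — reported as "strong", the reading this
package adopts for the top band.

## Parsimony

Unordered characters are scored by Fitch counting and ordered characters by
Sankoff dynamic programming with cost `|i - j|`; ambiguity sets are optional
leaf assignments minimized over, and missing cells never force a step. The
two scorers agree on unit costs, and both are cross-checked against an
independent implementation in the suite. `min_steps` (the best-case step
count used by the ensemble consistency index CI = Σmin/L) resolves
ambiguity by smallest hitting set (unordered) or shortest covering interval
(ordered), which brute force over ≤6 states makes exact.

The heuristic search runs random stepwise-addition replicates and then
swaps on the *whole pool* of equally short trees until closure, retaining up
to `maxtrees` topologies (auto-growing in steps of 100 by default, in the
style of the field's search programs). The default swapper is SPR applied
to the full pool (the implementation enumerates the complete SPR
neighbourhood, whose size `2(n-3)(2n-7)` the suite verifies exactly), with
NNI available as a cheaper option; pool-closure NNI alone was observed to
stall in a local optimum on one of the 50 seeded validation fixtures,
which motivated the stronger default. TBR is a possible future extension;
on matrices with hundreds of taxa it would matter more. Exhaustive
enumeration is available up to 9 taxa and is the oracle the heuristic is
validated against (50 seeded 6–8-taxon fixtures in the suite).

Bootstrap support resamples included characters with replacement (as column
weights), searches each pseudoreplicate with a reduced effort, and scores a
split by the percentage of replicates whose MPT strict consensus contains
it — support from replicate consensus rather than from the pooled MPT set,
matching common practice in parsimony software. Bremer decay is computed by
reverse-constraint search: the shortest tree *lacking* the split (found
exhaustively for ≤9 taxa, otherwise by penalized heuristic search) minus
the most-parsimonious length. A taxon set that is not a clade of the MPT
strict consensus is rejected with an error, since its decay would be
ill-defined.

## The synthetic-data generator

The generator stands in for specimen measurements: it emulates a pure-birth
(Yule) tree rescaled to a chosen depth in expected changes per character;
k-state characters evolved by the same rate matrices the likelihood uses,
with per-character gamma rates and, when `variable_only` is set, rejection
of constant characters — the whole character, its rate included, is
redrawn, so the simulation's ascertainment matches the Mkv conditioning
exactly (the suite closes this loop by comparing empirical pattern
frequencies on a 3-taxon star with the conditioned analytic probabilities).
Missingness and two-state polymorphism are injected at configurable rates;
Brownian-motion quantitative traits feed the median-binarization path, and
a multi-observation mode feeds majority coding. A metadata fixture mirrors
the shape of a large published character list (163 characters, 27
quantitative, 13 ordered, 4 excluded, 159 included) for bookkeeping tests.

Defaults are chosen to resemble a morphological matrix: state counts
dominated by binary characters (75% k=2, 20% k=3, 5% k=4), 10% of
multistate characters ordered, gamma shape 0.5 (strong rate heterogeneity),
and tree depth 0.8 expected changes per character from root to tip — deep
enough that basal internal branches carry tens of expected changes across a
few hundred characters, while per-character saturation between the most
distant tips stays moderate. What the generator deliberately does *not*
emulate: correlated characters, clade-specific rates, inapplicable-state
logic, or any real taxon sample — so passing recovery tests demonstrates
the estimators work under their own model assumptions, not that any real
matrix meets them.

## Problem sizes and numerical choices

The shipped tests run at deliberately modest sizes chosen as good
signal-to-noise compromises: enumeration oracles at 3–5 taxa; exhaustive
parsimony at 6–8 taxa; prior-only validation on 4 taxa at ~10^5 cycles; and
parameter recovery on 20 taxa × 300 characters at 10^5 cycles with two
independent runs. Likelihood agreement with enumeration is required to
1e-9; transition-probability rows sum to 1 within 1e-12; the harmonic mean
and ASDSF are exact arithmetic on the sample. Ties in stepwise addition are
broken uniformly at random under the search seed; identical seeds give
byte-identical outputs everywhere.

## Known limitations

* Single cold chain per run — no Metropolis coupling; very rugged
  posteriors would mix slowly (the cross-run ASDSF would reveal this).
* No SPR/TBR proposals or swappers (see rationales above).
* Unequal stationary frequencies, covarion behaviour and character
  correlation are out of scope.
* The harmonic-mean marginal likelihood estimator is known to be
  high-variance; it is provided because it is the field's conventional
  device for this analysis style, not because it is the best available
  estimator.
* The credibility-correction lookup is an approximate stand-in unless the
  user supplies the published table.
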