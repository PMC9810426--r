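---
title: "Inferring cultural transmission, mutation and trait genealogies on population networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cultural transmission, mutation and trait genealogies on population networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultree)
```

## The model

`cultree` models one discrete cultural trait — a custom, a dialect word, a
pottery style — evolving on a network of $n$ populations $P_1,\dots,P_n$.
Each population carries exactly one of $k$ states at any time; there is no
within-population diversity.  Time is discrete in human generations, and each
generation has two phases:

1. **Transmission.** Every population $P_i$ picks a source population
   (possibly itself) and copies its state of the previous generation.  The
   choice probabilities form a row-stochastic $n \times n$ matrix
   $A = (a_{ij})$, the weighted adjacency matrix of the network.
2. **Mutation.** The copied state then mutates: state $i$ becomes $j$ with
   probability $q_{ij}$, a row-stochastic $k \times k$ matrix $Q$.

Estimating all $n(n-1)$ transmission rates is hopeless, so $A$ and $Q$ are
parameterized by small families ([`transmission_spec()`],
[`mutation_spec()`]):

* **island** — complete graph, one inter-population rate $c$;
* **per-population** — per-node outward rates $c_1,\dots,c_n$;
* **gravity** — $a_{ij} \propto \pi_j e^{-d_{ij}^2/2\sigma^2}$: populations
  learn preferentially from large, nearby populations;
* **grid** — an $L \times L$ lattice where each square copies each
  side-neighbour with rate $d$ and itself with $1 - d\,\mathrm{deg}(P_i)$
  (degree 2, 3 or 4; no wraparound), requiring $d \le 1/4$;
* **explicit** — any validated row-stochastic matrix, for user-defined
  kernels.

For $k = 2$ with rates $q_{12}, q_{21}$ the matrix power has the closed form
used throughout the likelihood,
$$Q^t = \begin{pmatrix} \pi_2\lambda^t + \pi_1 & \pi_2 - \pi_2\lambda^t \\
\pi_1 - \pi_1\lambda^t & \pi_1\lambda^t + \pi_2 \end{pmatrix},
\qquad \lambda = 1 - q_{12} - q_{21},\;
\pi_1 = \frac{q_{21}}{q_{12}+q_{21}},\;
\pi_2 = \frac{q_{12}}{q_{12}+q_{21}},$$
and $(\pi_1, \pi_2)$ is the stationary distribution, the default prior on
the ancestral state.  The uniform mutation family spreads a total rate $\mu$
evenly over the $k - 1$ alternative states, i.e. $q_{ij} = \mu/(k-1)$ for
$i \neq j$: the division is by the number of *states*, not populations,
since it allocates the probability of leaving state $i$ among its
alternatives.

## Data, histories and genealogies

The data are the states of $m$ observed populations ($Y$); the states of $l$
further populations ($X$) may be flagged for inference, and remaining
populations are ignored.  The joint posterior targeted is
$$P(\theta_\tau, \theta_\mu, G, S, X \mid D) \propto
P(D, X \mid \theta_\mu, G, S)\, P(S \mid \theta_\mu)\,
P(G \mid \theta_\tau)\, P(\theta_\tau)\, P(\theta_\mu),$$
where $D$ combines $Y$ with the prior constraint that all traced copies
share an ancestor within $\tau$ generations.

The latent **history matrix** $G$ ($\tau \times n$) records, for each of the
past $\tau$ generations, the source from which every population copied;
under the model its entries are independent draws from the rows of $A$, so
$\log P(G \mid \theta_\tau) = \sum_{ij} c_{ij} \log a_{ij}$ with $c_{ij}$
the per-pair copy counts ([`transition_counts()`]).  Tracing the observed
copies backward through $G$ ([`trace_lineages()`]) merges lineages that meet
in one population — each population holds a single copy, so co-located
lineages share an ancestor, merging into a multifurcating node when three or
more arrive together.  The result is the single-trait genealogy: leaf ages
0, integer branch lengths, every ancestral node labelled with its
population.  Histories whose lineages fail to coalesce within $\tau$
contradict the prior bound and carry zero likelihood.

Row $1$ of $G$ is the copying event that produced the present generation.
The worked example shipped with the package (`example_history()`, also at
`inst/extdata/worked_history.csv`) is a six-generation history of five
populations in which any four present-day copies coalesce in population 3
five generations ago — a useful fixed point for validating any
reimplementation.

Given the genealogy, $P(Y, X \mid \theta_\mu, T', S)$ is computed by
Felsenstein's pruning recursion with transition matrices $Q^{t}$ per branch
([`pruning_likelihood()`]).  Computation is in log space with per-node
scaling; integer branch lengths keep every power exact (closed form for the
two-state family, repeated squaring otherwise, memoized per $t$).

## Samplers

The supplementary details of the original samplers for this model class are
not part of the package's sources, so the proposal kernels are the package's
own design, chosen to make Hastings ratios cheap:

* **Exact sampler** (`run_mcmc_exact()`), random-scan over:
  single $G$ entries proposed from the matching row of $A$ (the prior ratio
  cancels the proposal ratio, so entries off the traced lineages are
  accepted outright and cost nothing); whole columns redrawn from the prior;
  occasionally the whole matrix redrawn from the prior *conditioned on
  coalescence* — because the conditioning constant is state-independent it
  cancels too, leaving a pure likelihood-ratio acceptance.  This last move
  is an independence proposal from the genealogy prior and is what keeps
  tree-related quantities mixing on larger grids.  Continuous parameters use
  reflected uniform random walks inside their prior bounds (default step:
  1/10 of the prior range); the ancestral state $S$ is Gibbs-sampled from
  the root partial likelihoods, and each unknown state in $X$ is
  Gibbs-sampled given the rest.
* **Heuristic sampler** (`run_mcmc_heuristic()`): a pool of
  $(\theta_\tau, T')$ pairs is drawn from the prior by backward coalescent
  simulation (`build_prior_pool()`) — a lineage in $P_i$ moves to $P_j$
  with probability $a_{ij}$, co-located lineages merge — and the sampler
  proposes uniformly random pool entries, accepted by likelihood ratio; the
  transmission-parameter posterior is read off the accepted entries'
  attached draws.  Pool draws are conditioned on coalescence within the
  horizon (failed draws are discarded and redrawn), consistent with the
  definition of $D$; backward simulation is distributionally identical to
  tracing a prior-distributed history matrix, which the test suite verifies
  by exhaustive enumeration on a three-population instance.

Initialization draws the history from its coalescence-conditioned prior
(with a retry budget), parameters from prior means, unknown states from the
nearest observed neighbour.  Defaults: burn-in 10% of the chain, thinning
10, seeds mandatory.  Traced copies must sit in distinct populations — the
model assigns one state copy per population, and observed and target
populations are disjoint by construction, so duplicate leaves are rejected
rather than silently merged at age zero.

On large grids the transmission rate $d$ mixes far too slowly under the
exact sampler to be estimated jointly (its information enters only through
the $\tau \times n$ latent history); the documented default for such runs
is to hold $d$ fixed via `prior_fixed()`, which is exactly how the bundled
grid recovery study is configured.

## Synthetic data and the bundled studies

`simulate_forward()` is a first-class simulator of the generative process
(transmission draw then mutation draw per generation, order-stable and
bit-reproducible given a seed).  `simulate_grid_dataset()` wraps it for the
two-state grid studies.  What it emulates — and what it does not: the
generator produces exactly the model's own dynamics, so passing tests
demonstrate correct inference *under the model*; real cultural data add
within-population diversity, biased (non-neutral) copying, observation
error and non-stationary networks, none of which are represented.

The package ships two replica studies used by `scripts/acceptance.R` and
the acceptance tests, scaled down from their originals so a complete run
stays in the minutes range on one core:

* **Mutation-rate recovery** (`recovery_experiment()`): $6 \times 6$ grid,
  $d$ fixed at its true value 0.15, data simulated with
  $q_{12} = 0.04, q_{21} = 0.08$ over $10^4$ generations from a uniform
  random start (the mutation process alone mixes in
  $\approx 1/(q_{12}+q_{21}) \approx 8$ generations, so this is far past
  burn-in), 30 observed and 6 hidden populations, priors $U(0, 0.1)$,
  $\tau = 600$ (backward coalescence of all 36 lineages typically completes
  within $\sim$130 generations, 95% within $\sim$340).  Per replicate the
  central 95% credible intervals are checked against the true rates.  The
  reference design for this study observed 80 and hid 20 of $10^2$
  populations; the 30/6 split preserves the 80/20 proportion.
* **Genealogy reconstruction** (`genealogy_experiment()`): $4 \times 4$
  grid, all 16 populations observed, the genealogy of six focal copies
  (corners plus two interior squares) inferred with the heuristic sampler;
  data simulated with $d = 0.15$, $q_{12} = 0.01$, $q_{21} = 0.02$; priors
  $d \sim U(0.1, 0.2)$, $q \sim U(0, 0.03)$; $10^5$ prior trees (the
  original design used $5 \times 10^6$; the pool is an i.i.d. prior sample,
  so size trades Monte-Carlo resolution of tree space against memory and
  time with identical semantics).  The simulation is repeated with a bumped
  seed until the six focal copies are not monomorphic: the comparison of
  prior and posterior clades is about how data sort states into clades,
  which requires observable variation — this conditions the study on a
  property of the *design*, not on any test outcome.  Expected findings,
  both checked: posterior trees have an older MRCA than prior trees (small
  mutation rates need long branches to explain observed variation), and
  posterior clades group same-state leaves more often than prior clades
  (quantified by `clade_state_concordance()`).

The three-population instance (`tiny_instance()`: island network, $c = 0.3$
known, $\tau = 3$, two observed states and one target, $q_{12} = 0.1$,
$q_{21} = 0.2$ fixed at values that keep every marginal away from 0 and 1)
is small enough that `enumerate_posterior()` sums the posterior over all
$3^9$ histories and both root and target states exactly.  Both samplers are
required to reproduce its $X$, $S$ and TMRCA marginals within total
variation 0.02 (exact) and 0.03 (heuristic, pool $10^5$).

## Summaries

`posterior_state_marginals()` turns retained draws into per-population state
probabilities; `state_map()` merges them with the observations into a
spatial table ([`plot_state_map()`] renders it).  `clade_frequencies()` and
`mcc_tree()` summarize tree samples: the maximum clade credibility tree is
the *sampled* tree maximizing the product of its clades' sample frequencies
(log-product to avoid underflow; ties broken by first occurrence, making
the summary deterministic given a trace), with node supports and mean clade
ages annotated — the same semantics as the standard annotator tools, and
cross-checked against an independent implementation in the tests.
`effective_sample_size()` implements the initial-monotone-sequence
estimator of the integrated autocorrelation time.

## Numerical and design notes

* Degenerate mutation models are handled explicitly: $q_{12} = q_{21} = 0$
  makes $Q^t$ the identity, and absorbing or periodic chains make the
  stationary root prior undefined — an error asks for a fixed or uniform
  prior instead.  A proposed boundary value (e.g. $q_{12} = 0$ under a
  $U(0, 0.1)$ prior) yields a degenerate stationary prior and is rejected
  naturally through its $-\infty$ root-prior term when inconsistent with
  the current ancestral state.
* Likelihood-zero states (non-coalescing histories, conflicting states
  under zero mutation) propagate as $-\infty$ log terms, never as `NaN`.
* `-Inf` is a valid history log prior (forbidden transition used); explicit
  matrices are validated, never silently renormalized.
* Rows of $G$ older than the realized MRCA still contribute to
  $P(G|\theta_\tau)$ and are sampled as nuisance entries — they are
  off-lineage, so their updates are prior-accepted and cheap.
* All indices (populations, states) are 1-based everywhere in I/O.

## Limitations

Posterior distributions under uninformative priors are intrinsically broad
for this model class — a single trait simply carries little information —
so parameter estimates should be read as credible ranges, not point values;
informative priors are recommended for empirical use.  The exact sampler
does not estimate grid transmission rates in practical time (hold them
fixed); the heuristic sampler degrades when the leaf set is large, because
a finite prior pool then covers tree space too thinly.  Continuous-time
rate matrices, fractional generations, state-dependent (biased) copying,
rate heterogeneity across branches and partial/ambiguous observations are
out of scope.
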