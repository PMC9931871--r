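---
title: "Accessibility percolation on Cartesian power genotype spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accessibility percolation on Cartesian power genotype spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accperc)
```

## The model

A fitness landscape assigns a fitness value to every genotype; under strong
selection and weak mutation a population moves along *accessible paths*,
i.e. sequences of single mutations with strictly increasing fitness. The
House-of-Cards (HoC) model draws every fitness value i.i.d. from a standard
uniform distribution, so accessibility depends only on the rank order of
the values and the uniform choice is without loss of generality.

The genotype space is the $L$-fold Cartesian power $\mathcal{A}^L$ of an
*allele graph* $\mathcal{A}$: a finite simple directed graph whose vertices
are the allelic states of one locus and whose arrows are the permitted
single-step mutations. A genotype is a length-$L$ allele sequence; a
mutation changes one locus along an allele-graph arrow. The package ships
builders for the structures that cover the standard applications — the
complete graph (a free-for-all, giving Hamming graphs), the complete graph
with arrows into the wild type removed (irreversible first steps; for two
alleles, the directed hypercube), the path graph (forced mutation order),
and the amino-acid graph induced by single-nucleotide substitutions under
the standard genetic code — plus JSON/TSV readers for arbitrary graphs.

The central question: condition the endpoints on a fitness difference
$\beta = F_b - F_a \in (0, 1]$ and let $L$ grow with the endpoint distance
linear in $L$. The probability that $b$ is accessible from $a$ then jumps
from zero to a positive value at a critical $\beta_c$.

## The spectral core

For alleles $v, w$ and $t > 0$ define
$$\Gamma_{vw}(t) = \ln\left[(e^{tA})_{vw}\right],$$
with $A$ the adjacency matrix. The expected number of *quasi-accessible*
walks (walks counted with revisited genotypes re-randomised; one exists iff
an accessible path exists) between endpoints whose per-locus divergence
weights are $p_{vw}$ is exactly
$$E[\tilde Z] = L\,\bar\Gamma'(\beta)\, e^{L \bar\Gamma(\beta)},
\qquad \bar\Gamma(\beta) = \sum_{v,w} p_{vw}\, \Gamma_{vw}(\beta).$$
$\bar\Gamma$ is strictly increasing with a unique root $\beta^*$: below it
the expectation decays exponentially in $L$ (no accessible paths), above it
it explodes. For *regular* setups (below) $\beta^*$ is the true threshold,
approached at finite $L$ through
$$c_L = \hat\beta - \Gamma'(\hat\beta)^{-1} \frac{\ln L}{L},$$
and walk lengths at the threshold concentrate around $\mu L$ with variance
$\sigma^2 L$, where $\mu = \beta\bar\Gamma'(\beta)$ and
$\sigma^2 = \beta\bar\Gamma'(\beta) + \beta^2\bar\Gamma''(\beta)$.
Because $\beta^*$ is a difference of uniform quantiles, a root above 1
means the endpoint pair can never be accessible at linear distance; the
package reports this as a flag and never clamps.

```{r core}
s <- setup_hamming(graph_complete(4), delta = 1)
glance(solve_beta_star(s))
```

### Numerical choices

* **Matrix exponentials.** Symmetric adjacency matrices (all undirected
  builders) use one cached eigendecomposition, after which $e^{tA}$ at any
  $t$ is two small matrix products. General directed graphs — which may
  have defective adjacency matrices, e.g. nilpotent DAGs — use the power
  series $\sum_k t^k A^k / k!$ with cached powers and adaptive truncation
  order; since $A \ge 0$ and $t > 0$ every term is nonnegative, the series
  accumulates without cancellation and is accurate to machine precision on
  the log scale, which is the scale $\Gamma$ consumes. Entries that are
  structurally zero (no directed walk) are forced to exact zero from the
  reachability pattern, never left to floating-point dust, and unreachable
  pairs are reported as an explicit flag with $e^{\Gamma} = 0$, never as a
  large negative number.
* **Root finding.** The root of $\bar\Gamma$ is bracketed from $t = 1$
  (halving the lower edge until negative, doubling the upper until
  positive, cap $2^{60}$), solved by Brent's method and polished with
  Newton steps on the analytic derivative to a residual of $10^{-12}$.
  Monotonicity guarantees uniqueness, so bracketing cannot mislead.
* **Ties and degenerate inputs.** Fitness ties are a probability-zero
  event under a continuous distribution; the simulator breaks them by
  genotype index inside a stable sort. Setups that place divergence weight
  on allele pairs with no connecting walk are rejected by validation with
  the offending pairs listed.

## Regularity classification

The first-moment threshold is honest only if quasi-accessible walks are
not clustered onto a few initial and final segments. Martinsson's function
$\mathfrak{M}^*(s, r, \beta)$ splits each walk into three segments spanning
fitness fractions $\bar s r$, $s$ and $\bar s \bar r$ of $\beta$ and
averages the middle-segment growth rate with weights
$e^{\Gamma_{ax}(\beta\bar s r) + \Gamma_{xy}(\beta s) + \Gamma_{yb}(\beta\bar s\bar r)}$
over intermediate allele pairs $(x, y)$; terms with a structurally zero
middle segment contribute zero to numerator and denominator alike. It
vanishes at $s = 0$ and, at the solved root, at $s = 1$. A setup is
*irregular* if the function is positive anywhere off those two faces
(the first-moment threshold then undershoots the true one), *semi-regular*
if it is nonpositive everywhere, and *regular* if it is strictly negative
off the faces with a non-vanishing slope $\partial_s$ at $s = 1$.

Classification is numerical, as in the applications the framework was
built for: the default is a $200 \times 200$ lattice in $(s, r)$ with sign
tolerance $10^{-9}$ and a one-sided finite difference (step $10^{-5}$) for
the boundary slope, the most conservative value over the $r$ grid. Sign
violations narrower than the lattice cannot be detected; this caveat is
inherent to any grid test and is why `classify_setup()` records its
resolution. Positive regions are empirically thin slivers approaching the
$s = 1$ face, which is why `search_irregular()` — a best-effort exhaustive
enumeration of small digraphs — prescreens candidates on probe points
biased toward that face before paying for a full lattice. The smallest
irregular examples it finds have order 4 and sit above $\beta^* = 1$
(never accessible anyway); one of them is frozen as a test fixture.

```{r classify}
glance(classify_setup(setup_hamming(graph_complete(3), delta = 1),
                      grid_n = 60))
```

## The genetic-code application

For non-synonymous evolution the relevant allele graph has amino acids as
vertices, connected when a single nucleotide substitution converts a codon
of one into a codon of the other. The package builds this graph from the
standard genetic code (NCBI translation table 1, via Biostrings). Whether
the stop "amino acid" should be a vertex is genuinely open — biologically
a nonsense mutation is usually lethal, but as a graph vertex it still
provides mutational through-routes. Both variants are computable; the
stop-included 21-vertex graph is the default because its homopolymer
thresholds are the ones the package's acceptance checks pin to four
decimals (Tyr→Met $\beta^* = 0.4527$, walk-length factor $4.7567$;
Asp→Met $\beta^* = 0.4570$), while the 20-vertex variant gives visibly
different values (0.4829, 4.7426, 0.4682). Distances in this graph are at
most 3, with Tyr/Met the unique distance-3 pair.

## The House-of-Cards simulator

`draw_landscape()` / `estimate_accessibility()` realise the model the
analytic formulas describe: i.i.d. uniform fitness on every genotype of
$\mathcal{A}^L$, conditioned by pinning $F_a = 0$ and $F_b = \beta$
(shifting all values modulo 1 leaves the HoC ensemble invariant, so this
is equivalent to conditioning on the difference). Accessibility is decided
exactly by one sweep over genotypes in increasing fitness order,
propagating reachability along in-arrows; the witness path recovered from
predecessor pointers is automatically simple. The defaults *are* the study
conditions: endpoints at full divergence, interior fitness untouched, no
correlations — the simulator emulates pure HoC randomness and nothing
else. Passing tests therefore say nothing about landscapes with epistatic
correlation structure (NK-type or empirical), only that the analytic
machinery is faithful to the HoC model it was derived for.

Randomness is a counter-based stream per replicate, derived from the
master seed and the replicate index: replicates are order-independent,
results are reproducible bit-for-bit, and the interior fitness draws are
identical across $\beta$ values, which couples accessibility monotonically
in $\beta$ (raising the endpoint can only help). A second estimator
implements the equivalent Bernoulli view — each interior genotype survives
with probability $\beta$, ranks alone decide accessibility — and serves as
a cross-check of the conditioning, not as the default path. The genotype
space is capped at $10^6$ genotypes; the simulator refuses rather than
degrades.

Two exact oracles validate the stack from the other side:

* `enumerate_walk_expectation_oracle()` evaluates the quasi-accessible
  expectation by explicit walk counting on the product graph, term by
  term, converging to the closed form monotonically from below with a
  computable tail bound (`quasi_tail_bound()`).
* `exact_accessibility_small()` computes the accessibility probability by
  inclusion–exclusion over simple paths: a path subset whose interiors
  form $m$ vertices under the union of the paths' chain orders is jointly
  accessible with probability $\beta^m e/m!$, with $e$ the number of
  linear extensions, counted by dynamic programming over
  predecessor-closed subsets (a brute-force permutation count backs the DP
  in the tests). It refuses beyond 12 paths or 10 interior vertices.

### Desk-scale behaviour of the threshold

The asymptotic statements are about $L \to \infty$; the test suite probes
them at $L \le 14$ and $10^4$–$10^5$ replicates, sizes chosen so the whole
suite stays interactive. At those sizes the *lower* side of the threshold
is already clean — below $\beta^* - 0.15$ the estimated accessibility
falls with $L$ — and mean witness lengths at $\beta \approx c_L$ sit
within $\mu L \pm 3\sigma\sqrt{L}$ of the predicted moments. The *upper*
side is a weak threshold (a jump to a positive value, not to 1), and its
finite-size transient is non-monotone: between $L = 6$ and $L = 10$ the
estimate still decreases above $\beta^*$, turning upward only from
$L \approx 10$. The suite records both facts rather than pretending the
asymptotic ordering holds where it does not.

```{r sim}
sc <- threshold_scan(graph_complete(2), L_list = c(4, 6),
                     beta_grid = c(0.6, 0.8, 1), reps = 2000, seed = 7)
sc
```

## Known limitations

* Regularity classification is a lattice test; slivers finer than the grid
  or flatter than the tolerance escape it.
* The threshold function is resolved to its $\ln L / L$ term only; the
  order-$1/L$ window is not refined further.
* The simulator holds the full genotype space in memory (capped at
  $10^6$); asymptotic claims beyond desk scale are out of reach by design
  and are covered analytically instead.
* Only the extended-genotype-space *expectation* is used; the extended
  space itself is never materialised.
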