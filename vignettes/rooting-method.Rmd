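---
title: "Rooting phylogenies with a non-reversible substitution model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rooting phylogenies with a non-reversible substitution model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrroot)
```

## The problem

Most phylogenetic inference is carried out under time-reversible
substitution models because they make tree search tractable.  Reversibility
has a price: by the pulley principle, the likelihood of a reversible model
(with stationary root frequencies) is identical for every possible root
position, so the inferred tree is unrooted.  Downstream interpretation --
ancestral character states, the direction of trait change, the placement of
major clades -- usually needs a root.

`nrroot` roots an *existing* tree.  It takes an unrooted binary tree with
branch lengths in expected substitutions per site, plus the alignment the
tree was inferred from, and scores candidate root positions under the
unrestricted nucleotide model (UNREST), in which all 12 off-diagonal rate
matrix entries $\sigma_{xy}$ are free parameters.  UNREST is generally
non-reversible, so the likelihood *does* depend on where the root is, and
the best-supported position can be found by maximum likelihood.  This
splits the work the way practitioners usually want it: fast tree inference
under a reversible model, then a comparatively cheap non-reversible scan
for the root.

## The model

The generator $Q$ has off-diagonal entries $\sigma_{xy} \ge 0$ over
$\{A,C,G,T\}$ and diagonal entries $-\sum_{y \ne x}\sigma_{xy}$.  We rescale
$Q$ so that $-\sum_x \hat\pi_x Q_{xx} = 1$, where $\hat\pi$ is the
stationary distribution of $Q$; branch lengths then remain interpretable as
expected substitutions per site.  This normalization also removes the one
global scale redundancy of the 12 free rates.  Whether to normalize at all
is a genuine design choice (the likelihood surface over *rooting positions*
is unaffected); we normalize because the input branch lengths are declared
to be in substitutions per site.

Root base frequencies $\pi$ are free parameters, deliberately distinct from
$\hat\pi$: under a non-reversible process the composition need not be at
stationarity anywhere on the tree, least of all at the root.  Among-site
rate variation is the standard discrete-gamma scheme (`n_cats` categories
of equal weight, each represented by its conditional mean, renormalized to
mean 1) plus an optional invariant-sites class with proportion `p_inv`.
With the invariant class present, the gamma rates are scaled by
$1/(1-p_\mathrm{inv})$ so the overall mean rate stays 1.  A pattern
contributes to the invariant class only if all its unambiguous characters
are identical -- the usual +I convention.

Transition matrices $P(t) = \exp(Qrt)$ come from a complex
eigendecomposition of the (non-symmetric) $Q$.  When the eigenvector matrix
is ill-conditioned (condition estimate above $10^8$), we fall back to
scaling-and-squaring (`Matrix::expm`).  Entries are clamped to $[0,1]$ to
absorb $10^{-16}$-scale negatives from the complex arithmetic.

## Scoring a root position

A candidate root on a branch of length $t$ is parameterised by
$\beta \in [0,1]$: the branch is split into $\beta t$ and $(1-\beta)t$ and
a degree-2 root inserted.  For fixed model parameters the conditional
likelihood vectors (CLVs) of the two subtrees flanking the branch do not
depend on $\beta$, so the per-branch engine computes them once and
evaluates $LL(\beta)$ with just two fresh transition matrices per rate
class.  Pruning uses per-pattern log-scaling (triggered when a pattern
column's CLV drops below $10^{-200}$) so deep or long trees do not
underflow.

$LL(\beta)$ can be multimodal, and Brent-type root finding on the
derivative only locates extrema inside sign-change windows.  We therefore
(1) bisect $[0,1]$ recursively to depth 8 (256 subintervals) collecting all
windows where $\mathrm{d}LL/\mathrm{d}\beta$ changes sign, (2) run Brent's
method in each window, and (3) evaluate $LL$ at every derivative root *and*
at $\beta \in \{0, 1\}$, because a derivative root may be a minimum and a
boundary optimum has no interior sign change at all.  Near-ties (within
$10^{-10}$ log units) resolve to the smallest $\beta$ for determinism.  The
derivative itself is a central finite difference with step
$h = \max(10^{-7},\,10^{-5}\beta(1-\beta))$: an analytic derivative is
feasible but the bookkeeping cost outweighs the savings at the problem
sizes this package targets.

## Search mode and exhaustive mode

Model parameters always initialize at $\sigma_{xy} = 1/12$,
$\pi = 1/4$, $\alpha = 1$.

**Search mode** picks starting branches -- by default the top 1% (at least
one) of an approximate minimal-ancestor-deviation (MAD) ranking, or a
uniform random sample when clock-like bias is a concern -- and for each
start iterates: (a) optimize the substitution rates (L-BFGS-B on log-rates,
bounded to $[10^{-7}, 100]$), the root frequencies (L-BFGS-B on a softmax
parameterisation), and, every 10th iteration when gamma is enabled, the
shape $\alpha$ over $[\log 0.02, \log 100]$; (b) score the root at the
midpoint of every branch, fully optimize $\beta$ on the top 1%, and move
the root to the best placement.  Iteration stops when the log-likelihood
changes by less than `atol` ($10^{-4}$ by default), when early stopping
triggers, or after 500 iterations (a halting guarantee that is never
reached in practice).  Parameters are re-initialized at every start: the
rooting likelihood surface is known to have local optima, and cheap
re-initialization is the simplest defence.

The MAD-style ranking deserves a caveat: we use the mean, over all tip
pairs $(i,j)$ straddling a branch, of $|2d(m,i)/d(i,j) - 1|$ with the
candidate root $m$ fixed at the branch midpoint.  That is a deliberately
simplified screen (original MAD optimizes the root position per branch and
aggregates by rms); it is only ever used to choose *starting* branches, and
the random strategy is available where even that ranking might bias the
search.

**Exhaustive mode** runs the same optimization cycle on *every* branch,
re-initializing parameters per branch, and converts the per-branch
maximized log-likelihoods $\ell_i$ into likelihood weight ratios
$w_i = e^{\ell_i - \max_j \ell_j} / \sum_j e^{\ell_j - \max_j \ell_j}$.
The LWRs quantify root-placement uncertainty; they are reported in a table
and annotated onto the rooted newick output, suppressing branches with
$w < 10^{-4}$ to keep the output readable.

**Early stopping** (optional, both modes) terminates a branch's iteration
as soon as the best root lands on the same branch as in the previous
iteration with $|\Delta\beta| <$ `brtol` ($10^{-8}$ by default).  It trades
fully-converged likelihood values for speed; LWRs move very little (this is
checked in the test suite at a $10^{-2}$ bound), but reported likelihoods
should not be compared against other programs when it is on.

`atol` and `brtol` defaults are our choices -- the stopping rules need
values and the method's description names the knobs without fixing them.
The inner L-BFGS-B calls converge to roughly $10^{-8}$ relative precision
(`factr = 1e8`); running the inner optimizer tighter than the outer `atol`
sounds wasteful but is not, because a sloppy inner fit forces many more
outer iterations, each of which re-ranks every branch.

## Checkpointing

Exhaustive runs on large trees are long and per-branch independent, so the
driver can append each completed branch to a crash-safe log: 4-byte length,
serialized record, 4-byte Adler-32 checksum (computed by the package's own
implementation, which is validated against zlib's reference values in the
tests).  A restarted run keeps every complete, checksum-valid record and
re-schedules the rest; because each branch evaluation is deterministic and
self-contained, an interrupted-and-resumed run reproduces the
uninterrupted report bit for bit.

## The simulator and what the tests show

`random_rooted_tree()`, `random_model()` and `simulate_msa()` reproduce the
validation conditions used throughout: random-join rooted topologies,
i.i.d. exponential branch lengths with scale 0.5 substitutions/site,
UNREST rates drawn uniformly on $[0.01, 1.01]$ (spanning two orders of
magnitude, hence strongly non-reversible with high probability), root
frequencies from normalized exponential draws, and sites evolved
independently down the tree with per-site rate classes.  No indels are
simulated -- gaps are accepted on *input* (as fully-unknown states, like N
and the partial IUPAC ambiguity codes), but they carry no rooting signal
worth emulating.

The test suite checks, among other things: pruning likelihoods against
brute-force enumeration over all internal-node states ($10^{-10}$); the
equal-rates limit against the Jukes-Cantor closed form ($10^{-9}$); the
pulley principle as a negative control (reversible rates + stationary root
frequencies must make all branches equally good roots, and exhaustive LWRs
uniform); the $\beta$-optimizer against dense grid scans; and root recovery
on the simulation grid scaled down to 10-taxon trees with 1000 and 8000
sites, 20 replicates each, where the true root branch is recovered in the
majority of 8000-site replicates and the mean normalized topological root
distance (path node count between true and inferred root branches over
total node count) stays below 0.1.  These sizes are the package's chosen
desk-scale study conditions; the full-scale grids (up to 100 taxa, 100
replicates) behave the same way but are not run routinely.

Passing these tests shows the machinery is faithful to the model and the
search behaves as designed *under the simulator's assumptions*: a single
partition, no indels, no alignment error, branch lengths already in
substitutions per site, and data actually generated by a stationary UNREST
process.  Real alignments violate most of these at least mildly; the
exhaustive mode's LWR distribution is the tool for judging how much rooting
signal a real dataset carries.

## Known limitations

- Nucleotide data only; amino acids would inflate the free rates from 12 to
  380 and invite over-fitting.
- Single partition; no per-partition models.
- Multifurcating input trees are rejected rather than resolved.
- `p_inv` is held fixed (the optimization cycle covers rates, frequencies
  and $\alpha$ only), so +I is useful mainly with an externally estimated
  proportion.
- The likelihood engine is plain R; it is comfortable at hundreds of taxa
  and thousands of sites, but it is not a phylogenomics engine.
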