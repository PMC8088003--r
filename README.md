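# nrroot

Maximum-likelihood root placement for phylogenetic trees under a
non-reversible substitution model.

## What it does, and for whom

Trees inferred under the usual time-reversible models are unrooted: by the
pulley principle, every root position gives the same likelihood.  When a
rooted tree is needed -- direction of evolution, ancestral states, placing a
contested clade -- the common fixes (outgroups, molecular clocks) bring
their own artefacts.  `nrroot` takes the third route: score root positions
on an *existing* tree under the unrestricted nucleotide model (UNREST),
whose 12 free rates $\sigma_{xy}$ make it non-reversible, so the likelihood
genuinely depends on where the root is.

A candidate root on a branch of length $t$ splits it into $\beta t$ and
$(1-\beta)t$; the package maximizes over $\beta$ (bracketing + Brent on the
derivative, with endpoint checks) and over branches, either

- **search mode** -- a fast heuristic from a few starting branches (ranked
  by an approximate minimal-ancestor-deviation score, or chosen at
  random), returning the best root; or
- **exhaustive mode** -- every branch is evaluated and annotated with its
  **likelihood weight ratio** $w_i = e^{\ell_i-\max\ell}/\sum_j
  e^{\ell_j-\max\ell}$, quantifying root-placement uncertainty.

Discrete-gamma rate categories and an invariant-sites class (UNREST+Γ+I)
are optional.  Long exhaustive runs can checkpoint each completed branch to
a crash-safe append-only log (Adler-32 checksummed) and resume exactly.

Intended users: anyone with an unrooted tree (newick, branch lengths in
expected substitutions per site) and the DNA alignment it came from (FASTA
or PHYLIP).

## Worked example

Simulate a rooted 6-taxon tree and an alignment under a random UNREST
model, discard the root, and ask for it back with full uncertainty
quantification:

```r
library(nrroot)
rt  <- random_rooted_tree(6, seed = 42)     # truth: root on edge rt$edge
mod <- random_model(seed = 42)
aln <- simulate_msa(rt, mod, 1000, seed = 42)

fit <- root_fit(rt$tree, aln, mode = "exhaustive", seed = 1)
fit
#> Maximum-likelihood root placement (UNREST)
#>   6 taxa, 1000 sites (623 patterns), 9 candidate branches
#> Root placement report (exhaustive mode)
#>   best root: edge 9, beta = 0.0035 (split 0.002275 + 0.6389), logL = -7127.3778
#>   top branches by likelihood weight ratio:
#>     edge   9  LWR 0.3341  logL -7127.3778
#>     edge   6  LWR 0.3333  logL -7127.3802
#>     edge   5  LWR 0.3325  logL -7127.3826
#>     edge   2  LWR 0.0000  logL -7140.6857
#>     edge   1  LWR 0.0000  logL -7140.6870
rt$edge
#> [1] 9
```

The true root branch (edge 9) gets the highest support, and the LWR table
says something the point estimate alone would hide: three adjacent branches
are nearly equally plausible (LWR ≈ 1/3 each), i.e. the data pin the root
to a small neighbourhood, not to a single branch.  The fitted model is a
regular R fit object:

```r
round(coef(fit), 4)
#>     AC     AG     AT     CA     CG     CT     GA     GC     GT     TA     TC     TG
#> 0.1078 0.1049 0.0537 0.0836 0.1405 0.0383 0.1053 0.0159 0.0753 0.0872 0.0707 0.0802
#>      A      C      G      T
#> 0.0547 0.0317 0.3827 0.5309
logLik(fit)
#> 'log Lik.' -7127.378 (df=15)
```

`summary(fit)`, `plot(fit)` (LWR per branch), `simulate(fit)` (parametric
bootstrap alignments) and `rooted_tree(fit)` round out the interface.
Exhaustive fits also carry an annotated rooted newick
(`fit$report$newick`) with `[&LWR=...,alpha=...,LL=...]` comments on every
branch whose LWR is at least $10^{-4}$.

A command-line wrapper (`inst/scripts/nrroot.R`) exposes the same
functionality:

```sh
Rscript inst/scripts/nrroot.R --msa aln.fasta --tree tree.nwk --exhaustive \
    --output out   # writes out.rooted.nwk and out.summary.tsv
```

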