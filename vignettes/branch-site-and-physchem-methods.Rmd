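---
title: "Methods: branch-site selection tests and physicochemical divergence profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branch-site selection tests and physicochemical divergence profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomscan)
```

## The scientific problem

Opossums of the tribe Didelphini eat pitvipers and survive their
hemorrhagic venom. One venom component, the C-type lectin-like protein
botrocetin, attacks hemostasis by binding the A1 domain of von
Willebrand Factor (vWF) and promoting pathological platelet binding.
If venom drives adaptation in its target, the vWF gene of the resistant
clade should show (i) an excess of replacement substitutions on exactly
those lineages, concentrated in a subset of sites, and (ii)
physicochemical changes (charge, hydrophobicity) clustered at and near
the twelve A1-domain residues known from mutagenesis to contact
botrocetin.

`venomscan` implements both analyses as reusable, seeded, fully tested
components: a branch-site codon-model test of episodic positive
selection, and a comparative charge/hydropathy profile with rank-sum,
G, sliding-window and permutation-regression statistics.

## The branch-site model

Codon evolution follows a Goldman–Yang-type Markov process on the 61
sense codons. The instantaneous rate from codon $i$ to $j$ is zero
unless the codons differ at one nucleotide, and otherwise

$$q_{ij} \propto \pi_j \,\kappa^{\,[\text{transition}]}\,
\omega^{\,[\text{nonsynonymous}]},$$

with equilibrium frequencies $\pi$ from the F3x4 construction
(position-specific nucleotide frequencies, stop codons removed,
renormalized), transition/transversion ratio $\kappa$, and
nonsynonymous/synonymous ratio $\omega$.

Branches of the input tree are partitioned *a priori* into foreground
(the putatively resistant lineages, tagged `#1` in Newick) and
background. Sites fall into four latent classes:

| class | proportion | background $\omega$ | foreground $\omega$ |
|-------|------------|--------------------|---------------------|
| 0     | $p_0$      | $\omega_0 < 1$     | $\omega_0$          |
| 1     | $p_1$      | $1$                | $1$                 |
| 2a    | $p_{2a}$   | $\omega_0$         | $\omega_2 \ge 1$    |
| 2b    | $p_{2b}$   | $1$                | $\omega_2$          |

with $p_{2a} = (1-p_0-p_1)\,p_0/(p_0+p_1)$ and
$p_{2b} = (1-p_0-p_1)\,p_1/(p_0+p_1)$. The null model fixes
$\omega_2 = 1$; the alternative allows $\omega_2 \ge 1$. Twice the
log-likelihood difference is referred to $\chi^2_1$ — deliberately the
unmodified one-degree-of-freedom distribution rather than the 50:50
boundary mixture, which makes the test slightly conservative (our null
simulations bear this out: empirical size at $\alpha=0.05$ is well
below nominal).

Per-site likelihoods are computed by the pruning recursion over the
tree, with per-class rate matrices, pattern compression, and column
rescaling against underflow. The reversible rate matrix is
exponentiated through its symmetrized spectral decomposition. Both
routes are verified in the test suite against independent oracles:
full enumeration over internal-node codon assignments on small trees
(agreement to 1e-10 in log space) and a scaling-and-squaring series
expansion of the matrix exponential.

### A note on the null model and foreground labeling

Under $\omega_2 = 1$ the null *retains* the branch partition: class 2a
still has $\omega_0$ on background and $\omega = 1$ on foreground
branches. The null log-likelihood therefore legitimately depends on
which branches are labeled foreground (the two foreground schemes of a
typical study print different $\ell_0$). What is invariant, and what
the tests assert: class 2b coincides exactly with class 1 under the
null, and the whole mixture ignores the labeling whenever the class-2
mass is zero ($p_0 + p_1 = 1$).

### Rate scaling

Branch lengths are expected substitutions per codon under the fitted
mixture: each unscaled class matrix is divided by
$\rho = (p_0+p_{2a})\,r(\omega_0) + (p_1+p_{2b})\,r(1)$, the expected
rate averaged over classes with their background $\omega$, recomputed
at every parameter update. This keeps branch lengths comparable
between the null and alternative fits; exact agreement with any
particular external implementation's scaling convention is not claimed.

### Optimization

The likelihood is maximized with bounded quasi-Newton (`nlminb`) on
transformed parameters: $\log\kappa$, a multinomial-logit map for
$(p_0, p_1)$, a scaled logit for $\omega_0 \in (10^{-4}, 1)$, and
$\omega_2$ *untransformed* with box $[1, 999]$. The last choice is a
deliberate deviation from the more common $\log(\omega_2 - 1)$
transform: when the data favor $\omega_2 = 1$ (every null simulation),
the log transform sends the optimum to $-\infty$ on the working scale
and the optimizer crawls; the linear box reaches the boundary directly
and produced identical optima in every side-by-side comparison at a
third of the evaluations. Defaults: one fixed start
($\kappa=2, p_0=0.7, p_1=0.2, \omega_0=0.1, \omega_2=2$) plus five
seeded random restarts (seed 2011); convergence tolerance $10^{-8}$ on
the log-likelihood. Branch lengths are optimized jointly under the
null and then fixed for the alternative fit (the pipeline default;
both fits also accept free or fixed lengths explicitly). Degenerate
data (no variable sites) converge with $\omega$ unidentifiable rather
than erroring; non-convergence after all restarts is flagged on the
result, never silent.

### Site identification (BEB)

Posterior probabilities that each site belongs to a positively
selected class integrate parameter uncertainty over a discrete prior
grid: $(p_0, p_1)$ uniform over the probability triangle (10 category
midpoints per axis, inadmissible cells dropped), $\omega_0$ uniform on
$(0,1)$ (10 midpoints), $\omega_2$ uniform on $(1,11)$ (10 midpoints),
with $\kappa$, branch lengths and the rate scaling held at their MLEs.
Grid cells are weighted by their marginal data likelihood;
$P_{\text{selected}} = P(2a) + P(2b)$. A plug-in ("NEB") variant
evaluates the posterior at the MLEs only and is offered as a
documented fallback. Holding the scaling at the MLE (rather than
rescaling per grid cell) keeps branch lengths meaningful across cells;
this is a numerical choice the grid-marginalization is insensitive to
at the grid resolutions used.

## The physicochemical analysis

Charge assigns $+1$ to Lys/Arg, $-1$ to Asp/Glu, $0$ otherwise.
Histidine is neutral — the standard assignment at physiological pH —
with `histidine_charge = 1` available since the field sometimes
protonates it. Hydropathy is the Kyte–Doolittle scale. Per site, the
mean over resistant taxa minus the mean over non-resistant taxa gives
$\Delta$; gaps and `X` are excluded from means, and a site where
either group has no informative residue is dropped from every test
(never imputed).

* **Rank-sum**: Mann–Whitney U of the first-listed group with midranks
  (so W can be fractional under ties, as in the reference analysis's
  W = 216.5); exact null when untied and $n_1 n_2 \le 10^4$, otherwise
  normal approximation with tie and continuity corrections. Both group
  orientations are reported.
* **G-test**: $G = 2\sum O \ln(O/E)$ on the 2×2
  binding × selected table, df = 1, no Williams correction — this
  convention reproduces the reference value G = 8.61 from its printed
  counts (3/12 binding vs 4/193 non-binding at $P \ge 0.95$).
* **Sliding window**: centered moving average, default width 5
  (odd, configurable; the source analysis says only "site-by-site"),
  NA-ignoring, truncated at the edges.
* **Permutation regression**: observed OLS slope of $|\Delta|$ on
  linear distance (in residues, on reference coordinates — not
  alignment columns) to the nearest binding site; null slopes from
  1000 uniform permutations of $|\Delta|$ across sites with distances
  fixed; significance = falling outside the 2.5–97.5 percentile
  interval. Run with and without the binding sites themselves, per
  the original design.

Raw p-values are reported throughout; like the source analysis, no
multiple-testing correction is applied across this handful of planned
tests, and the reports say so.

## What the simulators emulate — and what they do not

`simulate_codon_alignment()` is the generative mirror of the
branch-site mixture: latent class per site, root codon from $\pi$,
exact transition sampling from $e^{Qt}$ per branch (or a Gillespie
path when an event history is needed, e.g. to count nonsynonymous
events against the generating $\omega$). Defaults follow the fitted
regime of the motivating study ($p_0 = 0.692$, $p_1 = 0.205$,
$\omega_0 = 0.054$, $\omega_2 = 6.79$); $\kappa = 2$ is a typical
mammalian nuclear-gene value, chosen once since the study does not
print its estimate. The bundled 26-leaf tree (`example_tree()`) is a
*synthetic stand-in* shaped like a didelphid phylogeny with a
nine-tip resistant clade and both foreground schemes pre-labeled;
its branch lengths are fixed, plausible values, not estimates.

`simulate_property_alignment()` draws one ancestral sequence, adds
i.i.d. background substitution noise per taxon (default 2% per site,
a realistic cross-mammal divergence for a conserved domain at this
alignment depth), and gives resistant taxa targeted replacements at
binding sites (and neighbors, with probability decaying as
$e^{-d/\text{decay}}$) that move charge by about 2 units and
hydropathy by about 6 units — the magnitude of a Lys→Glu or Gln→Val
change, the kinds of substitutions the study highlights. Group sizes
default to 4 resistant vs 22 non-resistant taxa, matching the shape of
the real comparison.

Neither simulator models indels, among-site rate variation beyond the
four-class mixture, alignment error, or phylogenetic correlation in
the amino-acid generator (taxa are exchangeable within groups). A
green test on synthetic data therefore establishes that the statistics
recover the structure they assume, at the stated effect sizes and
noise — not that real data meet those assumptions.

## Numerical choices and degenerate inputs

* Codon columns containing any non-ACGT symbol are missing data for
  that taxon (partial likelihood 1 over all states); IUPAC codes are
  not partially resolved. A stop codon before the last column is a
  validation error; a terminal stop is tolerated as missing.
* F3x4 can produce structural zeros (an unobserved nucleotide at a
  codon position); the likelihood engine clamps frequencies at
  $10^{-10}$ and renormalizes so the reversible decomposition exists.
  `estimate_f3x4()` itself reports the zeros unmodified.
* Taxon matching between alignment, tree and groups is exact and
  case-sensitive; mismatches are errors, never silent intersections.
* All coordinates in user-facing structures are 1-based inclusive
  (Mus mature-peptide numbering for vWF; A1 = 478–728, sequenced
  region 524–843); internal column indices convert at the I/O
  boundary.
* Every stochastic routine takes an explicit seed (default 2011) and
  restores the caller's RNG state.
* Percentile intervals use `quantile()` type 7; ties in permutation
  slopes at the interval endpoint count as inside.

## Known limitations

* Reproducing the motivating study's fitted values ($\hat\omega_2$ =
  6.79/8.31, W = 216.5/251.5) requires its accession-built alignment
  and original tree, which are not deposited in machine-readable form;
  the README documents the assembly recipe. The package's acceptance
  tests instead verify the printed arithmetic exactly and the
  statistical behavior (size, power, parameter recovery) by
  simulation.
* The branch-site fit optimizes branch lengths jointly only by
  quasi-Newton over all lengths; for large trees this is slow, and
  the simulation studies fix lengths at their generating values.
* Only the universal genetic code and F3x4 frequencies are
  implemented; F61 and alternative codes are out of scope.
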