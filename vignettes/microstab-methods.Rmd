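---
title: "Methods: community stability analysis of longitudinal microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community stability analysis of longitudinal microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstab)
```

## Scope and model

`microstab` analyses longitudinal OTU count tables — weekly swabs from a
cohort of participants — in two tiers. The community tier computes standard
ecology statistics: Hill-number alpha diversity, Bray-Curtis / Hellinger /
UniFrac dissimilarities, local contributions to beta diversity (LCBD),
phylogenetic community structure (NRI/NTI) under a richness null model, and
BVSTEP subset selection. The dynamical tier fits, per participant, a
generalized Lotka-Volterra (gLV) model to the core-community time series and
asks three questions of the fitted interaction network: is the interior
equilibrium locally stable, is the community permanent (globally stable),
and can a rare invader grow?

The continuous-time gLV model is

$$\frac{dx_i}{dt} = x_i\Big(r_i + \sum_j A_{ij} x_j\Big),$$

with $r_i$ the intrinsic growth rate of species $i$ and $A_{ij}$ the
per-capita effect of species $j$ on species $i$'s growth. Weekly sampling
makes the discrete-time analogue the natural data model, and we use the
Ricker map

$$x_i(t+1) = x_i(t)\,\exp\!\Big(r_i + \sum_j A_{ij} x_j(t) + \varepsilon_i(t)\Big),
\qquad \varepsilon_i(t) \sim \mathcal N(0, \sigma^2),$$

rather than an Euler discretization: taking logs of the ratio of consecutive
abundances turns the Ricker map into an exactly linear regression problem,
which is what the inference exploits, and the two discretizations coincide
for small steps. Noise is multiplicative (in the exponent) for the same
reason — it enters the log-linear regression additively.

## Inference (LIMITS-style bagged stepwise regression)

`limits_glv()` fits one regression per species. Over all consecutive-week
transitions where species $i$ is present at both endpoints, the response is
$y_i(t) = \ln x_i(t+1) - \ln x_i(t)$ and the candidate predictors are the
abundances $x_j(t)$ plus an intercept (which estimates $r_i$). The self-term
$x_i(t)$ is always in the model. Predictors are added by forward stepwise
selection: the candidate minimizing the *median held-out mean squared error*
across `n_bags` random train/test splits is admitted only if it improves
that error by more than `improvement_threshold` (relative). Final
coefficients are the elementwise median over bag fits; predictors never
selected contribute exact zeros to $A$, giving a sparse interaction matrix.

Choices a user should know about:

* **Defaults** `n_bags = 100`, `test_fraction = 0.5`,
  `improvement_threshold = 0` (any strict improvement admits a predictor),
  `min_samples = 9`. The nine-sample floor reflects the practical lower
  limit for inferring a one-step map from a weekly series. All settings are
  echoed into output sidecars.
* **Transitions** are only formed between weeks exactly one apart. A missed
  week breaks the chain; nothing is interpolated, because the regression
  assumes a one-step map.
* **Abundances** enter as fractions of the whole sample (relative
  abundances), consistent with `core_microbiota()` output, so states are
  comparable across participants. Whether counts or fractions are used
  changes only the scale of $A$, not the stability verdicts' signs.
* **Zeros** are excluded per species rather than pseudo-counted, avoiding
  log-of-zero artifacts at the cost of a few transitions.
* **Numerics:** a held-out error at machine-noise scale ($\le 10^{-24}$)
  stops the search — below that floor, "relative improvement" is rounding
  noise, and on noiseless data this is what keeps never-interacting pairs at
  exactly zero. Rank-deficient bag designs are dropped; candidate ties break
  lexicographically by OTU id.

A property worth stating explicitly: a trajectory that has settled onto its
equilibrium carries *no information* about $A$ (the design matrix is
constant). The package's recovery benchmarks therefore simulate short
noiseless segments from dispersed starts, separated by week gaps. At that
design, recovery of a 10-species stable matrix from 200 points is exact to
about $10^{-15}$, and with multiplicative noise $\sigma = 0.01$ the signs of
true interactions are recovered at 100% with Pearson $r > 0.99$ between
true and estimated entries (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`, which recompute these numbers).

## Stability, permanence, invasibility

`stability_report()` assembles the dynamical verdicts for a fitted (or
ground-truth) model:

* **Interior equilibrium** $x^* = -A^{-1} r$, flagged infeasible if any
  entry is non-positive (never clamped). Matrices with reciprocal condition
  number below $10^{-12}$ are rejected.
* **Local stability** uses the continuous-time Jacobian at $x^*$,
  $J = \mathrm{diag}(x^*)\,A$; the community is locally stable iff the
  dominant eigenvalue (maximum real part) is below $-10^{-9}$, with
  eigenvalues inside $\pm 10^{-9}$ reported as marginal. The dominant
  eigenvalue of $A$ itself is reported alongside, because stability
  statements about "the interaction matrix" are sometimes made about either
  matrix; for species absent at the equilibrium the Jacobian row reduces to
  the diagonal invasion growth rate.
* **Permanence** (no species tends to extinction from any interior start)
  is certified by Jansen's sufficient condition: a vector $p \ge 1$ such
  that $\sum_i p_i\,(r_i + (A\hat x)_i) \ge \delta$ at *every* boundary
  equilibrium $\hat x$ (the average Lyapunov function is
  $V(x)=\prod_i x_i^{p_i}$). Boundary equilibria are enumerated over all
  proper subsets (singular restricted systems skipped, negative solutions
  discarded, duplicates within $10^{-10}$ merged); enumeration is
  exponential and refused above `n_max = 20` species. The feasibility
  problem is solved as a linear program (`boot::simplex`) after substituting
  $q = p - 1 \ge 0$; constraint rows with negative right-hand side are
  flipped to $\le$ form because the solver requires non-negative constants.
  The margin $\delta = 10^{-6}$ and the normalization $p_i \ge 1$ make the
  LP numerically well-posed (the condition is scale-invariant in $p$). Any
  certificate is re-verified against every constraint before being
  reported, and `permanent = TRUE` additionally requires the dissipativity
  check. Because Jansen's condition is sufficient but not necessary, a
  `FALSE` verdict means "not certified", not "provably impermanent".
* **Dissipativity** is verified by an operational proxy: every
  self-limitation term $A_{ii}$ strictly negative, so each single-species
  subsystem has a finite carrying capacity. This is the package's stand-in
  for the boundedness hypothesis of the permanence theorem; the panel tests
  confirm by simulation that models passing it stay bounded.
* **Invasibility** follows the augmentation convention in which the invader
  gets an all-zero row and column (optionally a diagonal self-limitation
  `a_inv_inv`) and growth rate `r_inv`; the resident equilibrium is kept
  with the invader at zero, and the community is invasible iff the dominant
  eigenvalue of the augmented Jacobian exceeds $10^{-9}$. Note the spectral
  consequence of the literal zero-row/column convention: the augmented
  spectrum is exactly the resident spectrum plus $\{r_{\rm inv}\}$, so with
  `r_inv = 0` a locally stable resident is never invasible. The invader
  traits are therefore exposed as parameters rather than hard-coded.

## Community statistics

* **Hill numbers** $(\sum_i p_i^q)^{1/(1-q)}$ with the $q = 1$ continuity
  limit $\exp(-\sum p_i \ln p_i)$; computed on tables filtered at 5,000
  reads and rarefied to the minimum library size (filter, then rarefy, then
  diversity). $q = 0, 1, 2$ give richness, exponential Shannon entropy and
  inverse Simpson concentration.
* **Dissimilarities.** Bray-Curtis on counts; Hellinger as the Euclidean
  distance between square-rooted proportion vectors; UniFrac by
  branch-proportion accumulation in postorder (unweighted: branch length
  unique to one sample over the union; weighted:
  $\sum_b l_b |p_A(b)-p_B(b)| / \sum_b l_b (p_A(b)+p_B(b))$ on normalized
  proportions). The basal node of the tree is treated as the root, so star
  trees (root polytomies) are valid. Tests verify both variants against a
  brute-force per-branch oracle.
* **LCBD.** Gower-centring of squared dissimilarities,
  $G = -\tfrac12 C D^{(2)} C$; each sample's contribution is
  $G_{ii}/\mathrm{tr}(G)$, summing to 1. The default input is the Hellinger
  matrix (the pipeline also writes Bray-Curtis and UniFrac matrices, any of
  which can be fed to `lcbd()`), since LCBD theory is cleanest for
  Euclidean-embeddable dissimilarities.
* **NRI/NTI.** Observed mean pairwise distance (MPD) and mean
  nearest-taxon distance (MNTD) among OTUs present in a sample
  (presence/absence only, restricted to the `top_k = 1000` most abundant
  OTUs overall, ties broken lexicographically), standardized against 999
  draws of the same richness from the pool. NRI and NTI are the negated
  standardized effect sizes; values above 2 are flagged as strong
  phylogenetic clustering. Degenerate nulls (zero standard deviation, e.g. a
  sample containing the whole pool, or an equidistant star tree) yield `NA`
  with a warning — never a fabricated index. Null draws are seeded per
  sample by hashing the sample id with the master seed, so results are
  independent of processing order. Patristic distances are computed once
  into a leaf-by-leaf matrix; $O(k^2)$ memory is accepted at $k \le 1000$.
* **BVSTEP** forward-adds the OTU maximizing the Spearman correlation
  between subset and full lower-triangle dissimilarities, then
  backward-drops members costing at most $10^{-6}$, stopping at
  $\rho \ge 0.95$ by default. Spearman (rank) correlation is used, matching
  the BVSTEP tradition; the search is deterministic from an empty set
  (seeded random restarts are optional), the first member is always
  admitted (singleton matrices can be degenerate), and candidate ties break
  lexicographically. For Bray-Curtis the per-pair numerator and denominator
  are updated incrementally, making each evaluation linear in the number of
  sample pairs.

## The synthetic study generator

`make_study_fixture()` emulates the *structure* of a weekly oropharyngeal
cohort so that every stage is testable without any download: 30
participants by default (40% smokers — 12 of 30, matching an 18/12 cohort),
30 weekly samples each, a shared pool of 60 OTUs under a random coalescent
tree, and per-participant core communities of 5–12 OTUs following noisy
Ricker-map gLV dynamics. Models are anchored at a drawn equilibrium
($r = -A x^*$, self-limitation around $-5$ on the relative-abundance scale,
off-diagonal interactions at connectance 0.3), started near it, and
simulated with weekly log-noise $\sigma = 0.05$; reads are multinomial at
10,000 per sample with a fluctuating 5% background of non-core OTUs whose
per-OTU prevalence (~50%) keeps them below the 85% core threshold. Health
status is drawn per sample (7% cold, 3% antibiotics).

What the generator does *not* emulate: sequencing error and chimeras,
taxonomic misassignment, compositional coupling between participants,
overdispersion beyond multinomial sampling, and temporal autocorrelation in
health status. Passing tests therefore demonstrate that the algorithms are
correct on data obeying the model's assumptions — not that real
oropharyngeal dynamics are gLV.

## Problem sizes and tolerances used in validation

The validation suite runs the full study design (30 participants x 30
weeks, 999 null randomizations, 100 bags) end to end twice to confirm
byte-identical reruns; recovery benchmarks use 10 species x 200 time
points; the permanence panel uses 100 random 3–5 species models with 10
interior starts x 10,000 flow steps per certified model; concordance uses
50 models (25 stable draws, 25 feasible-but-unstable cyclic competition
models, whose instability is excited by an asymmetric 1% perturbation —
a symmetric perturbation lies in the stable eigenspace of those models).
Flow simulations use the exponential-Euler map with step $h = 0.05$–$0.1$,
which preserves fixed points exactly and the sign of local stability for
$h\,|\lambda| \ll 2$. Because a finite-horizon simulation cannot resolve
eigenvalues arbitrarily close to zero (nor represent arbitrarily fast ones
at a fixed step), the stable concordance panel is restricted to Jacobian
spectra with dominant real part $\le -0.05$ and modulus $\le 5$, and
"return" / "departure" are classified as contraction below 0.5% versus no
contraction below the initial 1% displacement over a time horizon of 200.

## Known limitations

* Permanence certification is one-sided (sufficient condition): absence of
  a certificate is not a proof of impermanence.
* Boundary-equilibrium enumeration limits the permanence test to communities
  of at most 20 species; inferred cores here are well under that.
* The gLV fit assumes one-step (weekly) Markov dynamics on relative
  abundances; long gaps reduce usable transitions, and compositional
  effects (a closed simplex) are not modelled explicitly.
* NRI/NTI inherit the usual sensitivity of null-model methods to pool
  definition; the abundance-ranked pool and richness null follow standard
  practice and are parameterized.
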