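---
title: "Probability models for ranking data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability models for ranking data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankery)
```

# The data model

A *ranking* of $k$ items is a permutation $\pi$ of $\{1,\dots,k\}$ in which
$\pi(i)$ is the rank given to item $i$ (1 = most preferred). Its inverse
$\pi^{-1}$ is the *ordering*: the list of items by rank position. A ranking
dataset is $N$ judges each ranking the same $k$ items; `rankery` stores it
either as an individual table (one row per judge) or aggregated (one row
per distinct ranking plus a frequency column `n`). All user-facing
functions accept either form and return tibbles, so analyses chain with
the pipe.

"Rank your top $t$" data are completed by mean-rank imputation
(`impute_partial()`): every unranked item receives the mean of the unused
ranks $\{t+1,\dots,k\}$. The completed rankings keep the total
$k(k+1)/2$; they are accepted by the descriptive statistics and by MDPREF
but are refused, with an explicit error, by all model-fitting functions
and by the pair/marginal matrices, whose definitions need strict
permutations.

## Descriptive statistics

`destat()` returns the mean rank $m_j = \frac1N\sum_i N_i \pi_i(j)$, the
pair matrix $P_{st} = \sum_i N_i\,I[\pi_i(s) > \pi_i(t)]$ and the marginal
matrix $M_{st} = \sum_i N_i\,I[\pi_i(s) = t]$. Two conventions coexist in
the literature for the direction of $P$: "the rank number of $s$ exceeds
that of $t$" (the indicator above, the default here) versus "$s$ is
preferred over $t$" (its transpose). Both satisfy
$P_{st} + P_{ts} = N$; `destat(direction = "beats")` selects the second
reading. Everything downstream that uses $P$ uses it symmetrically, so
the choice is cosmetic.

# Tests of uniformity

Uniformity means all $k!$ rankings are equally probable. The direct
$\chi^2$ test over all $k!$ cells is offered (`basis = "rankings"`) but
refused when the expected count $N/k!$ falls below five, which it almost
always does for $k \ge 5$. The practical tests are quadratic forms in the
low-dimensional summaries, scaled by the exact covariance of those
summaries under a uniform random permutation so that each is
asymptotically $\chi^2$ with the stated degrees of freedom:

* mean rank: $\frac{12N}{k(k+1)} \sum_j \left(m_j -
  \frac{k+1}{2}\right)^2$, df $k-1$;
* pairs: $12N\left[\sum_{s>t}\left(\frac{P_{st}}{N} - \frac12\right)^2 -
  \frac{1}{k+1}\sum_j \left(m_j - \frac{k+1}{2}\right)^2\right]$, df
  $\binom{k}{2}$;
* marginals: $N(k-1) \sum_{s,t}\left(\frac{M_{st}}{N} -
  \frac1k\right)^2$, df $(k-1)^2$.

The pairs form deserves a note: the pair proportions alone are not
asymptotically independent, and the subtraction of the mean-rank term is
exactly what reduces the quadratic form to the generalized inverse of the
uniform covariance of the $\binom{k}{2}$ pair indicators. The test suite
verifies this identity to $10^{-8}$ against an oracle built from the
eigendecomposition of that covariance (enumerated exactly over $S_k$),
and verifies by simulation at $k = 4$, $N = 200$ that all three
statistics have mean equal to their degrees of freedom and type-I error
at the nominal level.

## Comparing two datasets

`compare_rankings()` flattens the chosen summary (rank sums, pair counts,
or marginal counts) of each dataset into a $2 \times q$ table and applies
the standard contingency $\chi^2$ with $q - 1$ degrees of freedom
($q = k^2 = 49$ cells and df 48 for marginals at $k = 7$). Cells empty in
both datasets are dropped with a warning (they carry no information; the
df shrink accordingly); `zero_cells = "error"` refuses them instead. A
caveat documented deliberately: the cells of one judge are dependent
(each judge contributes a fixed total), so the contingency approximation
is *conservative* — its true type-I error sits somewhat below the nominal
level. The test suite checks validity (never anti-conservative) and
power, not exact nominal calibration, for this test.

# Model families

All model fitting requires complete strict rankings and $k \le 8$ (the
enumeration cap, `options(rankery.max_k = )`): every normalizing constant
and goodness-of-fit computation is an exact sum over $S_k$, which keeps
the whole package free of Monte-Carlo error in the likelihoods. At
$k = 8$ that is 40,320 permutations — still desk scale.

## Luce (Plackett–Luce)

Item $i$ carries a utility $V_i > 0$; a ranking is built stagewise, each
next-preferred item drawn with probability proportional to the utilities
still in play ("vase" sampling). `fit_luce()` maximizes the loglikelihood
in $\log V$ with the reference item's utility fixed at 1 — the paperless
constraint $V \ge 0$ leaves the scale free, and fixing one utility is the
cleanest identification. The loglikelihood is globally concave in
$\log V$, so quasi-Newton ascent from any start finds the global optimum;
the tests confirm the multi-start identity to $10^{-6}$. Degenerate
configurations (an item every judge ranks last) push the estimate to
$-\infty$; the fit flags `boundary = TRUE` and warns rather than failing.

## Rank-ordered logit

The covariate extension writes judge $n$'s utility for item $j$ as
$V_{nj} = \exp(\beta_{j0} + \sum_m \beta_{jm} x_{nm})$, reference item's
row fixed at zero. The exponential link is a deliberate design choice: a
linear link can produce negative utilities inside the stagewise
likelihood, whereas the log-linear form is the standard rank-ordered
logit of the discrete-choice literature. Standard errors come from the
observed information (numerical Hessian) and p-values are Wald z-tests.
Collinear covariates are rejected by name before optimization.

## Distance-based (Mallows-type)

$P(\pi \mid \lambda, \pi_0) = e^{-\lambda d(\pi,\pi_0)}/C(\lambda)$ for a
right-invariant distance $d$: Kendall's tau, Spearman's rho, rho-square,
or the footrule (`dtype` of `rank_distance()`). Right invariance makes
$C(\lambda)$ independent of $\pi_0$, with the classical product closed
form for Kendall's tau and exact enumeration otherwise; closed form and
enumeration are tested to agree to $10^{-10}$.

Fitting exploits a monotonicity: for fixed $\lambda > 0$ the
loglikelihood decreases in the frequency-weighted mean distance
$\bar d(\pi_0)$, so the MLE of $\pi_0$ minimizes $\bar d$ regardless of
$\lambda$, and $\lambda$ then solves a one-dimensional concave problem
(solved by `optimize` on $[0, 30]$; an estimate at the upper bound, which
happens when a single ranking is observed, triggers a warning, and
balanced data collapse to $\lambda = 0$). The modal ranking is searched
exhaustively for $k \le 6$ and by a pairwise-swap local search seeded at
the mean-rank ordering for $k = 7, 8$ (how the modal ranking should be
searched is genuinely open; exhaustive search is exact and the local
search trades that guarantee for tractability). Co-optimal modal
rankings are reported in `pi0_ties`.

## Phi-component

Kendall's tau decomposes into stages: $v_i$ counts the "mistakes" at
stage $i$ — items ranked below the stage-$i$ item of $\pi_0$ that $\pi$
nevertheless prefers ($v_i \le k - i$, $\sum_i v_i = $ tau). Giving each
stage its own dispersion yields
$P(\pi) \propto \exp(-\sum_i \lambda_i v_i)$ with the product closed form
$C(\Lambda) = \prod_i \frac{1 - e^{-(k-i+1)\lambda_i}}{1 - e^{-\lambda_i}}$.
Because $C$ factors over stages, the loglikelihood separates given
$\pi_0$ and each $\lambda_i$ is a private one-dimensional problem. Equal
dispersions recover the Mallows model exactly — tested as a likelihood
identity.

## Weighted distance-based

Rank-position weights $w_r \ge 0$ generalize each distance; for Kendall's
tau the discordant pair $(i, j)$ contributes
$w_{\pi_0(i)} w_{\pi_0(j)}$, and for the Spearman family the
displacement of the item holding rank $r$ under $\pi_0$ is weighted by
$w_r$. The weights absorb the dispersion scale, so the model has no
separate $\lambda$: $P(\pi) = e^{-d_w(\pi,\pi_0)}/C(w)$. A large $w_r$
says judges agree strongly about which item belongs at rank $r$.
Weight indexing is by rank position under the reference ranking — for
example, with $\pi_0 = (2,1,3)$ and $w = (10, 1, 1)$, disagreement about
item 2 (ranked first by $\pi_0$) is what the distance punishes.

Two numerical choices matter here. First, the likelihood surface in $w$
has a spurious stationary corner at $w = 0$ (the uniform distribution)
that traps arbitrary starting points; the optimizer is therefore seeded
at the equal-weight point matched to the unweighted fit's dispersion
($w_0 = \sqrt{\hat\lambda}$ for tau, $\hat\lambda$ for footrule and
rho-square, $\hat\lambda^2$ for rho), which lies on the likelihood ridge,
with a unit-weight start kept as a fallback. Second, because each
candidate modal ranking now needs a $k$-dimensional box-constrained
optimization rather than a one-dimensional one, the exhaustive $\pi_0$
sweep is used up to $k = 5$ only, with the pairwise-swap local search
beyond. When the generating weights are near zero below some rank, the
modal ranking is only weakly identified past that rank — the fit then
legitimately returns one of the near-equivalent modal rankings.

## Goodness of fit and model choice

`goodness_of_fit()` computes $\chi^2 = \sum_{i=1}^{k!} (O_i -
E_i)^2/E_i$ with $E_i = N P(\pi_i)$ over *all* rankings (unobserved ones
enter with $O_i = 0$) and df $k! - 1 - (\text{number of free
parameters})$ — the conventional count, adopted here explicitly since no
standard reference fixes it for these models. Expected counts that
underflow to zero make Pearson residuals undefined: the standalone
function errors, while the fitters degrade to a missing GOF with a
warning. `select_model()` picks the largest loglikelihood and attaches
the full comparison table.

# MDPREF

`mdpref()` centers the $N \times k$ rank matrix by the overall mean rank
$(k+1)/2$ and takes the SVD $X = UDV'$. Judges are rows of
$\sqrt{N-1}\,U$, items rows of $VD/\sqrt{N-1}$ — with this split
`judge_coords %*% t(item_coords)` reconstructs $X$ exactly at full rank,
which pins down which factor belongs to whom ($U$ has $N$ rows and must
be the judges). Per-dimension explained variance is
$D_{mm}^2/\sum_l D_{ll}^2$. SVD signs are fixed deterministically (the
largest-magnitude item loading of each dimension is made positive) so
repeated runs are identical. The plot (`autoplot()`) rescales judge
vectors by a single common factor purely for display; returned
coordinates are never rescaled.

# AHP

`ahp_weights()` takes a positive reciprocal comparison matrix, derives
weights as the principal eigenvector by power iteration (tolerance
$10^{-12}$) and reports Saaty's consistency ratio
$(\lambda_{\max} - k)/((k-1)\,RI_k)$ and Koczkodaj's worst-triad index.
The random index $RI_k$ is defined by simulation — the expected
consistency index of a random reciprocal matrix with upper-triangle
entries uniform on the 17-point scale $\{1/9,\dots,1/2,1,\dots,9\}$. The
bundled table (k = 3..15) was generated with
`simulate_ri(k, reps = 1e5, seed = 20260919)` and is stored as plain
code so it can be audited and regenerated; `ri =` overrides it.

# Label ranking

`local_knn()` predicts a new judge's ranking from the `knn_k` nearest
training judges (Euclidean distance on covariates, ties broken by
training index): a Luce model is fitted to the neighbourhood and items
are ordered by decreasing fitted utility. Tiny neighbourhoods routinely
produce degenerate Luce fits (an item never ranked above another); those
fall back to the neighbourhood's mean-rank ordering, which predicts the
same modal ordering where the Luce fit would have agreed. Covariates are
used unstandardized by default — Euclidean distance is scale sensitive
and silently rescaling would change neighbourhoods; `standardize = TRUE`
opts in. `local_knn_cv()` picks `knn_k` over a grid (default 1..20) by
seeded 10-fold cross-validation with total Kendall distance as the
error; ties prefer the smallest `knn_k`, and a fold whose prediction
fails is penalized with the maximum distance $\binom{k}{2}$ per judge.

# Synthetic data

`sample_luce()` draws from the vase process; `sample_dbm()` draws
exactly from the enumerated probability table of any distance-family
model (inverse-CDF over $S_k$ — exact rather than MCMC, which the
enumeration cap makes affordable); `make_rol_fixture()` adds
covariate-driven utilities (standard normal covariates, or shifted
clusters) for rank-ordered logit and label-ranking problems. Every
sampler takes a `seed` and restores the caller's RNG state, so fixtures
are reproducible without global side effects.

The generators emulate complete rankings of about seven items by a few
hundred judges, with optional judge covariates driving utilities — the
regime of the motivating kind of study (incentive-preference surveys).
They do not emulate real-data features such as top-$t$ censoring beyond
mean-rank imputation, tied or missing ranks, judge-specific attention
effects, or covariate measurement error. Passing tests therefore
establish correctness of the algorithms under the stated models, not
robustness of the models to those violations.

## Problem sizes used in validation

The shipped validation uses the sizes the methods are designed for:
calibration at $k = 4$, $N = 200$ with 2000 replicates; parameter
recovery at $N$ = 1000–3000 with $k = 4$; constant and normalization
oracles at $k \le 6$; exhaustive distance-axiom sweeps over all of
$S_4$; and a synthetic study of 566 judges ranking 7 items in the
acceptance script. These are the package's own choices of
representative, exactly checkable sizes.

# Known limitations

* All likelihood machinery is exact-enumeration based, hence the
  $k \le 8$ cap; large-$k$ rankings would need samplers and
  pseudo-likelihoods out of scope here.
* The two-sample comparison test is conservative (see above).
* Top-$t$ data are handled by imputation only; there is no top-$t$
  partial likelihood, and distances are not tie-aware.
* The weighted model's modal ranking is weakly identified at rank
  positions whose weights are near zero.
* AHP analysis covers a single comparison matrix; multi-judge
  aggregation should be done per judge and combined downstream.
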