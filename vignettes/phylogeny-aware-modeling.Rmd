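---
title: "Phylogeny-aware modeling of microbiome counts with mbtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-aware modeling of microbiome counts with mbtree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbtree)
```

## The data and the model

A microbiome survey produces a sample-by-taxon table of read counts, a
rooted phylogenetic tree whose leaves are the taxa, and a table of
per-sample covariates such as body mass index.  The counts are noisy,
sparse, unevenly deep across samples, and carry only relative
information.  `mbtree` models them *along the tree*.

### Dirichlet-tree multinomial (DTM)

Fix an internal node $v$ with children $1,\dots,k_v$.  The reads that
enter $v$ (the subtree sum of its leaf counts) are split among its
children by a Dirichlet-multinomial (DM): a multinomial whose
probability vector is itself drawn from a Dirichlet with parameters
$\alpha_v \in \mathbb{R}_{>0}^{k_v}$, which produces the
overdispersion that real count tables show.  Doing this independently
at every internal node defines the DTM: its likelihood factorizes into
one DM factor per node, so fitting decomposes into small independent
problems (`fit_dtm()`).  A sample whose count entering a node is zero
contributes nothing to that node's factor, because the factor is
conditioned on the entering total.

Three fitting forms are provided:

* **Maximum likelihood** per node, optionally with a ridge penalty
  $\lambda\|\log\alpha_v\|^2$.  The penalty shrinks toward the uniform
  prior $\alpha = 1$; it is expressed on the log scale so that it is
  consistent with the log link below and keeps estimates off the
  boundary.  The default is $\lambda = 0$.
* **Log-link regression**: $\alpha_v(x) = \exp(\beta_v^\top[1, x])$
  ties the node parameters to sample covariates
  (`fit_dtm(data, formula = ~ x)`).  Each node reports Wald standard
  errors from the observed information and a likelihood-ratio test
  against the intercept-only model on $p \cdot k_v$ degrees of
  freedom; p-values are reported raw and Benjamini–Hochberg adjusted
  across nodes, since every internal node is tested.
* **Zero inflation**: each child branch of a node is *structurally
  absent* with probability $\pi_{vj}$, independently across branches
  (the all-absent configuration is excluded by conditioning);
  conditional on the present set, counts follow the DM restricted to
  the present children.  The EM algorithm enumerates, for each sample,
  the possible present sets compatible with its zero pattern (an exact
  E-step; the number of uncertain children per sample is small in
  practice because only zero-count children are uncertain), updates
  $\pi$ as the posterior absence frequency and $\alpha$ by a weighted
  DM fit over present sets.  The observed-data log-likelihood is
  asserted non-decreasing at every iteration (tolerance $10^{-8}$);
  children that are never zero have $\pi$ fixed at 0.

### Numerical choices

Per-node likelihoods are maximized by quasi-Newton ascent on
$\log\alpha$ (unconstrained scale), started from a method-of-moments
estimate that matches the mean proportions and the overdispersion of
the observed proportions, with a uniform-start fallback.  $\log\alpha$
is boxed at $\pm 20$: beyond that the likelihood is flat to numerical
precision, and the difference $\log\Gamma(A) - \log\Gamma(A+n)$ would
suffer catastrophic cancellation (which an unbounded optimizer can
exploit as a spurious perfect fit).  For the same reason the
regression's linear predictor is clamped at $|\eta| \le 20$.  Note
that for underdispersed tables the DM likelihood has no interior
maximum: the fit then climbs toward the multinomial limit
($\alpha \to \infty$ at fixed proportions) and stops at the box, which
is the correct behavior — the attained log-likelihood, not the raw
$\alpha$, is the comparable quantity there.

## Empirical-Bayes relative abundances

Treating the fitted DTM as a prior — hyper-parameters estimated by
maximizing the data evidence, which for this model *is* the DTM fit —
the posterior mean of the composition is available in closed form by
conjugacy: at node $v$ the posterior branch probability for sample $i$
is $(\alpha_{vj} + y_{vij}) / (\sum_j \alpha_{vj} + \sum_j y_{vij})$,
and a leaf's abundance is the product of branch probabilities along
its root-to-leaf path (`ebay_compositions()`).  The estimate shrinks
each branch toward the prior mean, never to zero: zero-count taxa get
small positive abundances, deep samples converge to their empirical
proportions, and empty samples fall back to the prior mean.

Under the zero-inflated prior, a zero-count branch splits its mass
between "structurally absent" (abundance exactly 0) and "present but
unobserved" (the conjugate mean), weighted by the EM posterior of the
absence indicators; the reported composition is the posterior
expectation.  This is the coherent Bayes estimate; it can produce
estimates that are numerically indistinguishable from zero when the
posterior strongly favors absence, which is intended.

## Tree-guided penalized regression

Both regressions reparameterize the leaf coefficients through the
tree: with $A$ the binary leaf-by-node ancestor matrix (root excluded,
all other nodes in postorder), $\beta = A\gamma$, and an $\ell_1$
penalty on the node coefficients $\gamma$ selects whole subtrees at
once.

**TASSO** fits the linear log-contrast model

$$\min_{\beta_0, \gamma} \frac{1}{2n}\|y - \beta_0 - Z A \gamma\|_2^2
  + \lambda\|\gamma\|_1
  \quad\text{s.t.}\quad \mathbf{1}^\top A\gamma = 0,$$

with $Z = \log(\text{compositions})$ (strictly positive input — use
the eBay output).  The zero-sum constraint makes the fit invariant to
per-sample rescaling before closure, so only relative information is
used, and it forces selection to come in balanced groups:
subcompositions.

**Tree-guided fused lasso** drops the log transform and the
constraint: predictors are raw relative abundances (zeros are legal),
and a nonzero $\gamma_u$ at an internal node uses the aggregated
subtree abundance of $u$ as one predictor — its leaves are fused into
a taxon at a higher taxonomic level.  Penalty weights are 1 by
default (a subtree-size weighting can be supplied via `weights`).

### Solver

The solution is computed by cyclic coordinate descent on $\gamma$ with
covariance updates; the linear constraint is enforced by an
augmented-Lagrangian outer loop (multiplier update each outer
iteration, penalty parameter escalated tenfold whenever the violation
stalls above a quarter of its previous value).  Convergence is
declared at $10^{-7}$ on the coefficient change and $10^{-10}$ on the
constraint.  The inner loop is implemented in C++.  An independent
proximal-gradient solver (FISTA with an exact projection-prox computed
by bisection on the dual of the constrained soft-threshold) lives in
the test suite as an oracle and is never used by the package itself.

The $\lambda$ grid holds 100 log-spaced values from $\lambda_{\max}$
(the smallest $\lambda$ with a null solution, computed from the data;
for the constrained problem by minimizing
$\max_u |c_u - \nu s_u|/w_u$ over the multiplier $\nu$) down to
$10^{-3}\lambda_{\max}$.  Cross-validation (`lambda = "cv"`) uses
deterministic fold assignment from a required seed, k = 10 by
default, and selects `lambda.1se` (the sparsest model within one
standard error of the minimum) unless `cv_rule = "lambda.min"` is
requested.  Predictors are column-centered and the intercept is
unpenalized.

### Identifiability and reporting

Two degeneracies of the node parameterization matter in practice.

First, the ancestor matrix is collinear by construction: a node's
column is the sum of its children's columns.  When all children of a
node carry a common coefficient, the fit is reported with that mass
moved up to the parent (fewest nonzero nodes, preferring shallower
ones), matching the "taxa at multiple taxonomic levels" reading.
Second, in the fused model the compositional predictors sum to one
across each row, so $\beta$ is identified only up to a constant shift
absorbed by the intercept; fitted values and the objective are the
identified quantities.

TASSO's zero-sum constraint has a further structural consequence: the
exact solution usually carries tiny "slack" coefficients, orders of
magnitude below the selected components, that absorb the imbalance of
the dominant pair through cheap large-subtree columns.  (In the plain
leaf-level compositional lasso this cannot happen — every unit of
slack costs full $\ell_1$ price — but the tree columns make slack
cheap.)  `extract_subcompositions()` therefore (i) groups leaves with
equal nonzero coefficients into maximal node-aligned components, (ii)
separates genuine selections from slack at the largest
order-of-magnitude gap in component size, and (iii) pairs
opposite-signed components by sign balance (relative mismatch at most
0.25); balanced pairs are the detected subcompositions, and the slack
is reported in a final group flagged `balanced = FALSE`.

## The synthetic test bed

`simulate_benchmark()` defines the package's standard study: a random
binary tree with 16 leaves, 100 samples, sequencing depths drawn from
a negative binomial with mean 10,000 and size 5 (the depth scale and
spread of a small 16S cohort), symmetric Dirichlet parameters
$\alpha = 1$ at every node, no zero inflation, and a response
$y = 1.5\,(\log p_{T1} - \log p_{T2}) + \varepsilon$,
$\varepsilon \sim N(0, 0.5^2)$, computed from the *true* sampled
compositions.  `sample_dtm()` draws branch probabilities as normalized
Gamma variables and splits counts multinomially top-down, so row sums
equal the requested depths exactly; all generators are pure functions
of their seed.

The recovery studies reported by `scripts/acceptance.R` and asserted
in the test suite use these conditions:

* Dirichlet parameters: 8-leaf binary tree, true
  $\alpha_v = (2, 1)$ at every node, 200 samples at depth 5000,
  50 replicates.  The information bound gives each element a relative
  standard error near 0.1 at this size, so recovery is scored as the
  pooled share of elementwise errors within 20% (expected ≈ 0.95).
* Structural zeros: $\pi = 0.3$ on one leaf branch, 300 samples at
  depth 1000; the estimate should land within $\pm 0.1$.
* Log-link effect: $b = 0.5$ on one node of a 3-leaf tree, 300
  samples at depth 1000 — a size at which the Wald 2-SE interval
  attains close to its nominal coverage (it visibly under-covers at
  n = 100).
* TASSO: the default benchmark above; success means the detected
  subcompositions are exactly $\{\{T1\},\{T2\}\}$ with opposite
  signs under 10-fold CV.

What the generator does *not* emulate: taxonomic structure in the
tree (shapes are random), covariate-dependent zero inflation,
read-level noise (chimeras, sequencing error), or compositional biases
of library preparation.  Passing recovery tests therefore demonstrates
correctness of the estimators under the model, not robustness to
violations of it.

## A worked run

```{r workflow, eval = FALSE}
sim <- simulate_benchmark(seed = 1)
data <- sim$data

fit <- fit_dtm(data)                     # per-node DM parameters
comp <- ebay_compositions(data)          # posterior-mean compositions
reg <- tasso(comp, data$metadata$y, data$tree, lambda = "cv", seed = 1)
extract_subcompositions(reg)

## or, end to end with artifacts on disk:
run_pipeline(list(data = data, response = "y", seed = 1,
                  out_prefix = "results/benchmark"))
```

A COMBO-scale synthetic cohort (62 taxa, 98 samples, a BMI-like
response driven by four two-leaf log-contrasts) ships under
`inst/extdata/` as `synthetic_combo_*`; it is generated by
`scripts/make_synthetic_cohort.R` and is entirely synthetic — it
stands in for the real cohort the reference analysis used, which is
not redistributable here.

## Limitations

* Zero-inflated DTM *regression* (covariates on $\pi$) is not
  implemented, and the exact zero-inflation parameterization
  (branch-level, independent across branches) is one of several
  reasonable choices.
* The EM's exact E-step enumerates present sets and refuses nodes
  with more than 16 uncertain (zero-count) children in one sample;
  very sparse, highly multifurcating trees may hit this bound.
* Penalized fits come without inference (no p-values or intervals),
  and the subcomposition count at a CV-tuned $\lambda$ is
  tuning-sensitive by nature.
* Branch lengths are read and retained but unused by the models,
  which are topology-only.
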