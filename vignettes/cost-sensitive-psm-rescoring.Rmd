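---
title: "Cost-sensitive online kernel rescoring of peptide-spectrum matches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive online kernel rescoring of peptide-spectrum matches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csranker)
```

## The problem

A database search engine assigns every tandem mass spectrum a best-matching
peptide, producing one peptide-spectrum match (PSM) per spectrum. Most of
these matches are wrong, and post-search rescoring must separate the correct
target matches from the incorrect ones using the search attributes
(`xcorr`, `deltacn`, `sprank`, `ions`, `hit mass`) plus derived attributes
(`enzN`, `enzC`, `numProt`, `deltacnR = deltacn/xcorr`). The target-decoy
construction supplies a labelled negative class: matches against a reversed
or shuffled database (decoys) behave statistically like the incorrect target
matches, which both licenses the FDR estimate and supplies training labels.

Treating rescoring as plain supervised classification fails in a specific
way: every decoy label is right, but a large fraction of the "+1" target
labels is wrong. On *hard* datasets -- those where only a small fraction of
targets is correct -- methods that trust the target labels degrade badly.

## The model

The ranker fits a kernel discriminant $f(x) = \sum_{j \in S} \alpha_j
k(x_j, x)$ (Gaussian kernel $k(u,v) = \exp(-\|u-v\|^2 / 2\sigma^2)$, no
intercept) by minimizing

$$
\tfrac12 \lVert w \rVert^2
 + C_1 \sum_{i \in \Omega_-} h\!\left(y_i f(x_i)\right)
 + C_2 \sum_{i \in \Omega_+} R_s\!\left(y_i f(x_i)\right),
$$

where $h(t) = \max(0, 1-t)$ is the hinge loss on decoys and
$R_s(t) = \min(1-s,\, \max(0, 1-t))$ is the *ramp* loss on targets. The two
asymmetries are the model's substance:

* **Cost sensitivity.** A decoy scored positive is a certain error, so decoy
  losses carry the larger weight ($C_1 \ge C_2$). A target scored negative
  may simply be an incorrect match, so target losses carry less weight.
* **Bounded target losses.** The ramp plateau $1-s$ caps the loss of any
  single target, so incorrect targets -- which sit deep on the wrong side --
  cannot dominate the fit the way they would under an unbounded hinge.

This objective is equivalent to a weighted formulation in which each target
carries a reliability weight $\theta_i \in [0,1]$ and a selection-pressure
parameter $\lambda$ controls how many targets effectively participate; the
correspondence is $s = 1 - \lambda/C_2$. The package parameterizes the model
through $s$ directly because $s$ has a bounded, interpretable range; the
implied $\lambda = C_2(1-s)$ is stored on the parameter object. $s$ is
restricted to $(-1, 1)$: $s < 1$ keeps the ramp non-degenerate and $s > -1$
keeps its plateau below two hinge units, so a single mislabeled target can
never outweigh two decoy errors.

Writing $R_s = H_1 - H_s$ with $H_s(t) = \max(0, s-t)$ splits the objective
into convex and concave parts, and the concave-convex procedure (CCCP)
minimizes it by alternating two steps: fix the linearization flags
$\eta_i = \mathbf 1\{y_i f(x_i) < s\}$ over targets, then solve the convex
subproblem exactly through its Lagrange dual

$$
\max_{A \le \alpha \le B}\;
 -\tfrac12 \alpha^\top K \alpha + \langle \alpha, y\rangle
 + C_2 \textstyle\sum_{i \in \Omega_+} \eta_i ,
$$

with per-coordinate boxes $[-C_1, 0]$ for decoys, $[0, C_2]$ for targets
with $\eta = 0$, and $[-C_2, 0]$ for targets with $\eta = 1$. A target with
$\eta_i = 1$ has been judged unreliable by the current fit and is allowed to
push the discriminant *down*, exactly like a decoy but with the smaller
weight. There is no equality constraint (no intercept), so single-coordinate
ascent steps are exact: $\alpha_i \leftarrow \mathrm{clip}(\alpha_i + g_i /
K_{ii},\, [A_i, B_i])$ with gradient $g_i = y_i - \sum_j \alpha_j K_{ij}$.

The printed form of the Gaussian kernel in the source literature lacks the
negative sign in the exponent; the package implements the standard
$\exp(-\|u-v\|^2/2\sigma^2)$, the only reading that yields a bounded,
positive-semidefinite kernel.

## Two solvers

`cs_ranker(..., solver = "batch")` runs full-batch CCCP with the exact
coordinate-ascent inner solver (KKT tolerance $10^{-5}$), warm-started
across outer iterations and stopped when the $\eta$ vector stabilizes. Its
memory is quadratic in $n$; it exists as the reference and oracle.

`solver = "online"` (default) implements the one-sample-per-round active-set
algorithm. Per round it:

1. refreshes $\eta$ and the dual boxes for all active targets from the
   current fit, clipping any $\alpha$ its new box excludes;
2. **PROCESS**: inserts the incoming PSM with $\alpha = 0$;
3. **REPROCESS**: repeatedly takes the exact coordinate step on the worst
   box-KKT violator until the violation is below `tol` ($10^{-3}$ by
   default) or a per-round cap (100) is reached;
4. **CLEAN**: when the active set exceeds `M`, removes up to
   $\lfloor m_{\mathrm{frac}} |S| \rfloor$ points that have $\alpha = 0$
   *and* satisfy their KKT condition, largest $|g|$ first -- the points most
   firmly locked at their bound. Removing only zero-coefficient points
   leaves the discriminant unchanged everywhere, which is the invariant that
   makes CLEAN safe.

Kernel storage is a dense block over the active set only, so memory is
$O(|S|^2) \le O(M^2)$ and never $O(n^2)$. Defaults `M = 1000` and
`m_frac = 0.35` follow the method's published operating point. A finishing
REPROCESS pass (enabled by default) polishes the final iterate to tolerance.
The visiting order is a fresh seeded permutation per epoch; one epoch --
every PSM seen once -- is the default. Ties in the violator argmax and the
CLEAN ranking break toward the lowest index, so a fixed seed reproduces the
trajectory exactly.

### Initialization of the concave-part flags

Both solvers start every target at $\eta = 0$ (plain hinge treatment) and
let the per-round (online) or per-outer-iteration (batch) refresh flip
$\eta$ from the *informed* fit. The alternative -- evaluating
$\eta_i = \mathbf 1\{y_i f(x_i) < s\}$ at $f \equiv 0$ or at a point's
arrival -- is degenerate: with $s \ge 0$ it marks every target unreliable
before the model has seen any signal, all dual boxes become non-positive,
and the fit collapses into the all-negative optimum it can never leave (no
$\eta$ can flip back once every $f < 0$). Under the hinge start, a target
flips to $\eta = 1$ only when the fit -- including the point's own
contribution -- places it below $s$, which in practice flags exactly the
incorrect-target population. For $s \le 0$ and an empty model the two rules
coincide.

## Scores, selection and calibration

Fitted PSMs are scored by $\mathrm{score} = \tfrac{2}{\pi}\arctan f \in
(-1, 1)$, a monotone map kept for comparability of score distributions
across datasets. Selection at a nominal level uses the target-decoy
estimate $\widehat{\mathrm{FDR}} = 2D/(D+T)$ over ranking prefixes (ties
rank decoys first, conservatively), monotonized from below into q-values so
that "the largest selection with estimated FDR at most the level" is
well-defined even where the running ratio is non-monotone. The reported
achieved FDR is the q-value at the cutoff and never exceeds the nominal
level. `fmr_report()` computes the entrapment false match rate
$N_{\mathrm{entrapment}}/N_{\mathrm{target}}$ among selected targets, with
entrapment membership flagged by a protein-identifier prefix
(`"entrapment_"` by default), an FDR-independent quality check.
`margin_projection()` provides the two-coordinate rotation (a Householder
reflection sending $(1,1,0,\dots)$ to the classifier normal) used to
visualize a linear classifier's margin region in the 9-attribute space.

## Parameters that matter

* `C1`, `C2` (default 2, 1): loss weights, unitless; `C1 >= C2` enforced.
  Raising `C1/C2` hardens the decoy side; it matters most when correct
  targets are rare.
* `s` (default 0): ramp truncation. Larger `s` discards doubtful targets
  more aggressively (`lambda = C2 (1 - s)` shrinks).
* `sigma` (default 3): kernel bandwidth *on the weighted, standardized
  feature scale*. Features are z-scored and weighted (1.0 for `xcorr` and
  `deltacn`, 0.5 for the rest), giving a mean inter-PSM distance around 2.7;
  `sigma` well below that memorizes the null -- support vectors wrap
  individual incorrect targets, training-set scores separate them from the
  decoys they are exchangeable with, and FDR calibration breaks. The default
  sits at the scale where the fit generalizes; `cv_tune()` searches
  {1, 2, 3} by default.
* `M`, `m_frac` (1000, 0.35): active-set cap and CLEAN fraction. CLEAN may
  leave $|S| > M$ if fewer removable points exist (support vectors are never
  dropped; removing one would change $f$); storage grows as needed in that
  case.
* Z-score standardization precedes weighting because the raw attributes mix
  scales by orders of magnitude (`hit_mass` in the thousands, `deltacn`
  in hundredths); a Gaussian kernel over raw attributes would see only mass.
  Constant columns map to zero. The training normalization is stored on the
  fit and re-applied by `predict()`.

Cross-validated tuning (`cv_tune()`) follows the method's published
protocol: 3 stratified folds, objective = held-out targets identified at
the nominal FDR (held-out counting penalizes the overfitting the method is
prone to on its own training scores), ties toward the least complex point
(smaller `C1`, then `C2`, then `sigma`, then `s`).

## The synthetic generator

`simulate_psms()` generates the two-population structure that the
target-decoy construction assumes: decoys and incorrect targets are drawn
from one shared null distribution over all nine attributes -- making them
exchangeable by construction, which is precisely the assumption licensing
$2D/(D+T)$ -- while correct targets (a fraction `pi_correct` of targets)
are shifted by `effect` null-SDs on `xcorr` and `deltacn`, are fully
tryptic with probability `p_enz_correct` = 0.9 (vs 0.3 for null matches),
and concentrate on few proteins (about 20 PSMs per protein), raising
`numProt`. Null attribute families: truncated Gaussians for `xcorr` and
`deltacn`, `1 + Poisson(3)` for `sprank` (correct targets:
`1 + Poisson(0.3)`, concentrated at rank 1), `Beta(2, 6)` for `ions`,
`N(1500, 200)` for `hit mass` (an opaque pass-through column). Peptide
strings and flanking residues are generated consistently with the tryptic
flags so the feature-derivation path is exercised end to end. Presets worth
naming: `pi_correct = 0.5` resembles a routine dataset; `pi_correct = 0.1`
a hard one.

What the generator does *not* emulate: spectrum-level structure, mass-error
physics, charge states, retention time, shared-peptide ambiguity, or the
heavy-tailed attribute correlations of real search output. Tests passing on
this generator certify the solvers, the selection machinery and the
calibration logic under the exchangeability assumption -- not performance
on any real instrument's output.

## Numerical choices and degenerate inputs

KKT tolerances: $10^{-5}$ (batch inner), $10^{-3}$ (online rounds and
finishing pass). Coordinate steps use $K_{ii} = 1$ exactly (Gaussian
diagonal). A zero-variance feature column standardizes to zero rather than
NaN. `xcorr = 0` makes `deltacnR` undefined and is a per-row error by
design (search engines do not emit zero cross-correlations; a zero signals
a malformed export). Rows with missing required fields are dropped and
counted, mirroring blank-record removal in practice. An empty active set
gives $f \equiv 0$. The `eta` tie at $y f = s$ uses the strict inequality
(flag stays 0). `alpha = 0` is tested at $10^{-12}$ when CLEAN collects
removable points.

## Problem sizes used in the test suite

The bundled tests run entirely on generated data: unit fixtures of 3-120
PSMs; solver-equivalence checks on 100-300 PSMs against a full-batch oracle
and an interior-point QP reference (`kernlab::ipop`); recovery and
calibration runs on 2,000 PSMs (`pi_correct = 0.3`, `effect = 2`, five
seeds) and hard-preset comparisons on 1,200 PSMs (`pi_correct = 0.1`).
These sizes exercise every code path, including CLEAN at reduced `M`, while
a full run of the suite stays in the minutes range. The published operating
point (`M = 1000`) is the package default for real tables, which commonly
reach $10^5$ PSMs and beyond -- the online solver's memory does not grow
with that count.

## Known limitations

* Training and scoring on the same PSMs (the method's standard mode)
  carries a residual self-confirmation bias; the held-out split
  (`train_frac`) and `cv_tune()`'s held-out objective are the built-in
  mitigations, and the entrapment FMR is the independent audit.
* The batch solver is quadratic in memory and is not intended beyond
  ~20,000 PSMs.
* `hit mass` is passed through as an opaque numeric attribute; no mass-error
  modelling is attempted.
* Protein-level inference, posterior error probabilities, and reading
  native search-engine binary formats are out of scope; input is a
  delimited table (TSV/CSV or a PIN-style dialect).

## A worked example

```{r example, eval = FALSE}
library(csranker)
d <- simulate_psms(n_target = 1000, n_decoy = 1000, pi_correct = 0.3,
                   effect = 2, seed = 100)
fit <- cs_ranker(d, fdr_levels = c(0.02, 0.04), seed = 1)
summary(fit)
evaluate_against_truth(fit$selections[[1]]$selected,
                       d$records$is_correct, fit$label)
```
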