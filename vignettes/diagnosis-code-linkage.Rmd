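---
title: "Linking de-identified patient records with diagnosis codes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking de-identified patient records with diagnosis codes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dxlink)
```

## The problem

Research datasets are routinely de-identified: names, dates of birth and
other protected health information are stripped before the data are shared.
When the same patients contribute to two such datasets — say a disease
registry and an EHR extract — there is no common identifier left to join
them on. What both datasets usually *do* retain is each patient's set of
diagnosis codes (ICD-9/ICD-10), binarized to ever-recorded / never-recorded.
Diagnosis profiles are close to unique within a cohort, so they carry enough
signal to link records probabilistically, provided the two sources share
enough diagnosis information and the model tolerates *discrepancies*: codes
legitimately recorded in one source and not the other (different time spans,
different care sites, billing idiosyncrasies).

`dxlink` implements a Bayesian matcher built for exactly this situation,
together with the machinery needed to use and to evaluate it: hyper-parameter
estimation, a Fellegi–Sunter latent-class comparator, a simulator of linked
sparse binary code matrices with known ground truth, and TPR/PPV scoring.

## The matching model

Let $A$ hold $n_A$ records and $B$ hold $n_B$ records over $K$ aligned
binary codes, with $A_k(i), B_k(j) \in \{0,1\}$. For a candidate pair the
per-code log-likelihood ratio of match against non-match is

$$\mathcal{L}_k(a,b) =
  \mathbf{1}_{a=1,b=1}\log\frac{1-\varepsilon_k^-}{\pi_{Bk}} +
  \mathbf{1}_{a=0,b=0}\log\frac{1-\varepsilon_k^+}{1-\pi_{Bk}} +
  \mathbf{1}_{a=1,b=0}\log\frac{\varepsilon_k^-}{1-\pi_{Bk}} +
  \mathbf{1}_{a=0,b=1}\log\frac{\varepsilon_k^+}{\pi_{Bk}},$$

where $\pi_{Bk}$ is code $k$'s prevalence in $B$,
$\varepsilon_k^- = P(B_k=0 \mid A_k=1, \text{match})$ and
$\varepsilon_k^+ = P(B_k=1 \mid A_k=0, \text{match})$ are the discrepancy
rates. The pairwise similarity is the naive-Bayes sum
$\mathcal{L}(ij) = \sum_k \mathcal{L}_k(A_k(i), B_k(j))$. Unlike a plain
agreement count, these weights scale with prevalence: agreeing on a rare
code is strong evidence, agreeing on the absence of a rare code is almost
none. That asymmetry is what makes the method work on sparse code data
where the classical Fellegi–Sunter agreement weight fails.

Each record of $A$ is then matched against the $n_B$ candidates *plus an
explicit no-match category*:

$$\pi_{ij}(A\to B) = \frac{\exp\{\mathcal{L}(ij)+\operatorname{logit}\pi_0\}}
 {1+\sum_{\ell=1}^{n_B}\exp\{\mathcal{L}(i\ell)+\operatorname{logit}\pi_0\}},$$

with $\pi_0$ the prior probability that a random cross-dataset pair is a
match; the symmetric quantity $\pi_{ij}(B\to A)$ normalizes down each
column. The final posterior is the average
$\hat\pi_{ij} = \{\pi_{ij}(A\to B)+\pi_{ij}(B\to A)\}/2$, and a pair is
declared when $\hat\pi_{ij} \ge \alpha$. The softmax over a whole row means
the method uses *all* records at once: a tie between two identical
candidates is split 0.5/0.5 rather than double-declared with certainty, and
one-to-one structure is encouraged without a hard assignment step.

Numerically, the $n_A \times n_B$ similarity matrix is computed through the
exact decomposition
$\mathcal{L} = \sum_k w_{00,k} + r\,\mathbf{1}^\top + \mathbf{1}\,c^\top +
A\,\mathrm{diag}(d)\,B^\top$
(three BLAS products instead of an $n_A n_B K$ loop), and posteriors are
evaluated in log space with a max-shift: with thousands of codes,
$\mathcal{L}$ routinely reaches several hundred and naive exponentiation
would overflow. The unit tests pin the decomposition against a literal
triple-loop oracle at $10^{-10}$ and the normalization (row mass plus
no-match mass equals one) at $10^{-12}$.

## Hyper-parameters: what is estimated and how

* **Prevalences** $\pi_{Bk}$: per-code sample fractions in $B$, clipped to
  $[1/(2n_B),\, 1-1/(2n_B)]$ so codes absent from one dataset (the default
  alignment is the *union* of codes seen in either dataset) cannot produce
  infinite weights.
* **Discrepancy rates**: a user-supplied scalar is the primary path —
  0.01 for both $\varepsilon^-$ and $\varepsilon^+$ in all reference
  analyses here. Matching quality is insensitive to the exact value as
  long as codes are sparse; a low $\varepsilon^-$ is generally right
  because a code recorded once is unlikely to be missing from the other
  source. `estimate_discrepancy_rates()` offers an opt-in rough estimate
  from high-similarity pairs (those above $c_0$, below).
* **Prior match probability** $\pi_0$: the observed similarities follow a
  mixture $\pi_0 g + (1-\pi_0) f$ with $f$ the (dominant) non-match
  component. `auto_pi0()` fits a four-parameter Azzalini skew-t to the
  similarity sample by maximum likelihood, locates the rightmost inflexion
  point $c_0$ of the fitted density (central second differences on a
  10,001-point grid spanning the sample range widened by two fitted
  scales), and estimates $\pi_0$ as the fraction of pairs with
  $\mathcal{L}(ij) > c_0$, clamped inside $(0,1)$ by one pair's worth of
  mass. The skew-t likelihood is maximized by bounded quasi-Newton on
  $(\xi, \log\omega, \alpha, \log\nu)$ with $\nu \in [1,200]$ and
  multi-starts from moment estimates, because skew-t likelihoods are
  multimodal in small samples; samples beyond $5\times 10^6$ pairs are
  sub-sampled (seeded) before fitting.

**How rough is $\hat\pi_0$, and why that is acceptable.** For *any*
unimodal skew-t, a non-trivial share of its own probability mass
(4–16% depending on skewness and tails) lies beyond its rightmost
inflexion point. Since the exceedance fraction is bounded below by
$(1-\pi_0)P_f(>c_0)$, the estimator has a floor of a few percent
regardless of how small the true $\pi_0$ is: in our simulations with 0.1%
true overlap it returns values around 2–10%. This makes $\hat\pi_0$ an
order-of-magnitude device, not an estimate to report. It is retained
because the *matching* is insensitive to it: the similarity gap between
true and false pairs in code-rich data spans tens of log-units, so any
$\operatorname{logit}\hat\pi_0$ in a wide band declares the same pairs.
Users who know their expected overlap should pass `pi0` directly; the
package's accuracy claims rest on TPR/PPV, which the acceptance tests
measure, not on $\hat\pi_0$ itself.

## The Fellegi–Sunter comparator

The classical baseline treats the $K$ per-code *agreement* indicators
$\gamma_k = \mathbf{1}\{A_k(i)=B_k(j)\}$ as a latent-class model: agreement
probability $m_k$ among matches, $u_k$ among non-matches, match proportion
$p$, fitted by EM over all admissible pairs, then scores
$\sum_k [\gamma_k \log(m_k/u_k) + (1-\gamma_k)\log\{(1-m_k)/(1-u_k)\}]$.
Crucially — and deliberately — it counts a $(0,0)$ concordance exactly like
a $(1,1)$ concordance, so on sparse code matrices almost every pair agrees
on almost every code and the score carries little signal; that failure mode
is precisely what the Bayesian weights repair, and the test suite asserts
the $(0,0)$/$(1,1)$ equivalence holds of this implementation. Two decision
rules are provided: the plain threshold (`fs_match_all`) and the
one-to-one variant (`fs_match_best`) that keeps only scores maximal in both
their row and their column (ties kept), with a row-only mode for
sensitivity since "largest score per patient" is ambiguous between the two
readings. Blocking on an external label restricts the admissible pairs.

EM implementation notes: with no blocking, every E- and M-step sum is
evaluated exactly through the identity
$\gamma_k = 1 - a - b + 2ab$, which turns all pair sums into matrix
products — the $n_A n_B K$ agreement array is never formed, and a
500×300×1000 fit takes a fraction of a second. With blocking, the
admissible pairs are streamed as an explicit list, optionally compressed by
grouping identical agreement patterns (the default when $K \le 64$); the
tests verify that the bilinear, streamed and compressed paths and a naive
reference EM all coincide. Initial values are $m_0 = 0.9$, $u_0$ the
empirical per-code agreement rate, $p_0 = 1/\max(n_A,n_B)$; convergence is
declared at a maximum parameter change below $10^{-6}$ (500 iterations
cap, non-convergence is a warning, never an error); parameters are clipped
to $[10^{-6}, 1-10^{-6}]$. The degenerate case where all pairs agree on a
single code drives $m$ and $u$ to the clip boundary and is reported as an
identifiability warning.

## The simulator

`generate_base_matrix()` produces the base cohort: per-code prevalences
drawn from a heavy-tailed Beta(0.3, 6) (many rare codes, a few common
ones), then a Gaussian-copula threshold model with a one-factor latent
correlation (pairwise latent correlation 0.2 by default) so codes co-occur
the way comorbidities do. Two calibration choices deserve explanation:

* `mean_codes` rescales the sampled prevalences so the expected number of
  codes per patient hits a target. The simulation-study replication uses
  `mean_codes = 5` over $K = 1000$ codes, emulating claims data where a
  one-year extract shows ~5 codes per patient across thousands of
  possible codes. Without it the raw Beta prevalences give ~0.05·K codes
  per patient — a richer, EHR-like regime used where the tests need
  unambiguous profiles.
* All-zero rows are redrawn: a patient appears in a claims or EHR extract
  *because* at least one code was billed, so a zero-code patient is not a
  realizable observation. (A side effect worth knowing: conditioning on
  ≥1 code induces a mild Berkson-type negative dependence that is only
  noticeable when the whole panel has a handful of codes.)

`perturb_records()` creates the second, discrepant copy:
$X^* = \mathbf{1}\{X \odot Z_1 + (1-X)\odot Z_2 > 0\}$ with
$Z_1 \sim N(\mathbf{1}, \rho\Sigma)$, $Z_2 \sim N(-3\cdot\mathbf{1},
\rho\Sigma)$ drawn independently per patient ($Z_1$ and $Z_2$ are two
independent draws; the two distinct distributions in the formula are read
as two draws). $\Sigma$ defaults to the base matrix's empirical code
correlation — which need not be PSD after filtering, so negative
eigenvalues are floored at zero and a shared eigen-factorization is reused
across patients. The construction is intentionally asymmetric: at
$\Sigma = I$ a present code flips with probability
$\Phi(-1/\sqrt\rho)$ (≈0.16 at $\rho=1$) while an absent code appears with
probability $\Phi(-3/\sqrt\rho)$ (≈0.0013 at $\rho=1$) — losing a code
across sources is common, gaining one is rare. $\rho = 0$ returns the
input bit-for-bit. `split_overlap()` then takes partially overlapping
subsets with re-randomized identifiers and returns the ground-truth pairs.

What the simulator does *not* emulate: real ICD hierarchies (sibling codes
substituting for one another), visit-level longitudinal structure, and
site-specific coding habits. Passing tests on simulated data therefore
demonstrate the algorithmic claims (exactness, normalization, flip-rate
calibration, comparative behaviour of the two matchers) — not clinical
performance on any particular pair of real datasets.

## Evaluation and the replication grid

`evaluate_matches()` scores a declared set against a 1-1 truth set by exact
pair intersection: TPR = TP / |truth|, PPV = TP / |declared|, with a zero
denominator reported as missing rather than zero. `run_experiment_grid()`
replicates the simulation study: for each grid cell (noise $\rho$, code
count, rare-code filter, overlap fraction) and replicate it simulates a
linked pair, runs the Bayesian matcher at cutoffs 0.5 and 0.9 and the
Fellegi–Sunter comparator (plain and one-to-one at score threshold 0), and
returns a long table. Replicate seeds are derived deterministically from
the master seed and recorded in the output. Inside the grid the EM budget
is capped at 100 iterations at tolerance $10^{-5}$ — the comparator's PPV
is flat in the tail iterations and the cap keeps a five-replicate grid
under ten minutes on one core.

Problem sizes used by the shipped checks: the replication grid runs five
replicates of $n_A = 500$ vs $n_B = 300$ (150 true pairs) over $K = 1000$
calibrated codes at $\rho = 0.5$; the zero-noise exact-recovery check runs
200 vs 100 patients over $K = 500$ uncalibrated codes. On these, the
Bayesian matcher at $\alpha = 0.5$ shows TPR well above 0.5 with PPV near
1, the 0.9 cutoff trades TPR for PPV in every replicate, and the
one-to-one Fellegi–Sunter comparator stays below 20% PPV.

## Design choices made where the design was open

* **Code alignment**: union of codes seen in either dataset (absent codes
  become all-zero columns), intersection available; order is
  lexicographic, and all outputs reference patients and codes by
  identifier, never by position.
* **Ties at the threshold**: $\hat\pi_{ij} = \alpha$ counts as a match
  (the rule is $\ge$). When one record faces two identical counterparts,
  both pairs are reported at posterior ~0.5 each; no tie-break is
  invented.
* **Clipping**: prevalences to half an observation, discrepancy rates and
  EM parameters to $10^{-6}$ — every log-weight stays finite by
  construction, and the choice is a flag (`clip = FALSE` turns boundary
  values into errors instead).
* **One-to-one rule**: row-and-column maximality, with `mode = "row_only"`
  for sensitivity.
* **Skew-t parameterization**: the Azzalini form, implemented in the
  package (density, sampler, MLE) since the fit, the inflexion search and
  the $\pi_0$ estimate form one tightly coupled procedure.

## Known limitations

* $\hat\pi_0$ is rough by construction (see above); treat it as an order
  of magnitude. Sensitivity to $\pi_0$ should be checked when profiles
  are information-poor.
* Patients with one or two codes — especially common codes — are close to
  unmatchable in principle: their match evidence may not overcome any
  sensible prior, and two such patients can collide. In regimes where the
  mean prevalence is large relative to $\varepsilon$, very sparse patients
  can even be matched through concordant *absences*. Perfect recovery at
  zero noise is therefore a property of cohorts with distinctive profiles,
  not of arbitrary ones.
* Counts are ignored: the model is binary by design; a count-likelihood
  extension is out of scope here.
* The Fellegi–Sunter EM is fitted on all admissible pairs under conditional
  independence; with a single informative code or fully concordant data it
  is unidentifiable (warned, not repaired).
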