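---
title: "Split-manuscript trials: design, scoring and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-manuscript trials: design, scoring and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(manusplit)
```

## The design

A split-manuscript trial evaluates a writing intervention — here, a
CONSORT-based writing aid shown while drafting a manuscript — by randomizing
*within* each participant. Every participant writes the six methods-section
domains of one randomized-trial protocol (trial design, randomization,
blinding, participants, interventions, outcomes); three domains are
allocated to the writing-aid condition and three to usual writing. Each
participant therefore acts as their own control, exactly as in split-mouth
dental trials and cluster randomized cross-over trials, and the domain
score is the unit of analysis.

With 3 of 6 domains per condition there are $\binom{6}{3} = 20$ allocation
patterns. `generate_sequence()` randomizes in permuted blocks of 20 — each
complete block contains every pattern exactly once — so any
multiple-of-20 prefix of the sequence assigns each domain to each condition
for exactly half the participants.

```{r}
alloc <- generate_sequence(41, seed = 20140429)
table(alloc$condition[alloc$participant_index <= 20],
      alloc$domain[alloc$participant_index <= 20])
```

## The outcome: weighted keyword scores

Completeness of reporting of a written domain is measured against a
pre-specified rubric: a list of keywords (content elements that should be
reported), each with a positive weight $w_i$ and an `essential` flag. With
credited indicators $x_i \in \{0, 1\}$ the domain score is standardized to
a 0–10 scale,
$$ S = 10\,\frac{\sum_i w_i x_i}{\sum_i w_i}, $$
which makes scores comparable across rubrics of different lengths and
weight scales; multiplying all weights by a constant leaves $S$ unchanged.
A keyword is credited when it is present **or** when the writer explicitly
flagged the information as missing from the source protocol
(`flagged_missing`) — a writer cannot report what the protocol does not
contain, and saying so is complete reporting. The essential-elements
subscore applies the same formula to the essential subset and is undefined
(`NA`, not 0) when a rubric has no essential keywords.

Keyword presence is judged by two independent raters; `merge_consensus()`
copies agreements, applies explicit adjudications to disagreements, and
reports anything left unresolved rather than deciding it silently. Exactly
two raters are supported — the consensus rule for more raters would be a
voting scheme this design never used. `auto_match()` provides a
deterministic substring matcher (case-folded, punctuation stripped) so
synthetic pipelines can run end to end; it makes no attempt at natural
language understanding.

## The model and the primary estimator

Scores are modelled as
$$ y_{pgj} = \mu + \beta T_g + b_p + c_{pg} + e_{pgj}, $$
with a fixed intervention effect $\beta$, a random participant effect
$b_p \sim N(0, \sigma_b^2)$, a random participant-by-condition effect
$c_{pg} \sim N(0, \sigma_c^2)$, and residual $e_{pgj} \sim N(0,
\sigma_e^2)$, $j = 1..m$ domains per condition. The implied correlations
are
$$ \rho = \frac{\sigma_b^2 + \sigma_c^2}{\sigma^2} \quad\text{(same
condition)}, \qquad \rho' = \frac{\sigma_b^2}{\sigma^2} \quad\text{(across
conditions)}, $$
with $\sigma^2 = \sigma_b^2 + \sigma_c^2 + \sigma_e^2$.

Because the design is balanced (every participant has exactly $m = 3$
scores per condition), the generalized-least-squares solution for $\beta$
collapses to the paired contrast: with $d_p = \bar y_{p,tool} - \bar
y_{p,control}$,
$$ \hat\beta = \bar d, \qquad \widehat{se}(\hat\beta) = \frac{sd(d_p)}{\sqrt N}, $$
with t-based inference on $N - 1$ degrees of freedom. `primary_effect()`
implements this closed form rather than an iterative mixed-model fit: it is
exact, has no convergence failure mode, and the package's tests verify the
identity against an independent REML fit (`lme4::lmer`) to relative
tolerance $10^{-6}$ on simulated balanced trials. The identity holds for
interior REML fits; when a variance component is estimated on the boundary
the REML standard error is no longer the GLS one, so singular fits are
excluded from the comparison (they are rare at $N = 40$ under the study's
variance assumptions). The degrees-of-freedom convention ($N-1$) follows
the paired-contrast reduction. No multiplicity adjustment is applied
anywhere.

`fit_variance_components()` recovers $(\sigma_b^2, \sigma_c^2, \sigma_e^2)$
by ANOVA method of moments from the three mean squares of the balanced
layout, truncating negative solutions at zero with a `truncated` flag.
Per-domain comparisons are independent across participants (each
participant contributes a domain to exactly one condition), so they use
classical equal-variance Student t-tests. The ancillary comparison against
published reports pairs scores within (protocol, domain), averages within
protocol, and draws inference from between-protocol variability on
$n_{protocols} - 1$ df — again the balanced-case closed form of the stated
random-protocol-intercept model.

## Sample size

The calculation follows the cluster randomized cross-over method. The
unrounded two-sample requirement per group,
$n_0 = 2 (z_{1-\alpha/2} + z_{power})^2 \sigma^2 / \Delta^2$, is multiplied
by the design effect (inflation factor)
$$ IF = 1 + (m - 1)\rho - m\rho', $$
then rounded **up** to a multiple of $m$ so it converts to whole
participants. Inflating first and rounding once removes the ambiguity of
intermediate rounding (rounding $n_0$ first happens to give the same
answer at the default parameters, but that is a coincidence of these
numbers, not a rule).

```{r}
params <- design_params(alpha = 0.05, power = 0.90, delta = 2, sigma = 4,
                        rho = 0.8, rho_prime = 0.4, m = 3)
inflation_factor(params)
required_sample_size(params)
```

`analytic_power()` is the matching normal-approximation power,
$\Phi\!\big(\Delta / (\sigma\sqrt{2\,IF/n}) - z_{1-\alpha/2}\big)$. Note a
deliberate asymmetry: the analytic formula uses normal criticals (as
sample-size formulas do), while the simulated power of the actual analysis
uses the $t_{N-1}$ reference distribution. At $N = 40$ participants the
exact paired-t power is about 1.5 percentage points below the normal
approximation (0.891 vs 0.905); `simulate_power()` reproduces the former,
`analytic_power()` the latter, and the package documents rather than hides
the gap.

## The synthetic-data generator

`generate_trial()` realizes the model above directly: allocation from the
package's own permuted-block randomization, then
$y = \mu_{control} + \beta T + \delta_d + b_p + c_{pg} + e$, with variances
from `variance_components_from_icc()`. Defaults are fixed at the study
conditions: $N = 40$, $\mu_{control} = 5.0$, $\beta = 2.1$ (the observed
condition means), $\sigma = 4$, $\rho = 0.8$, $\rho' = 0.4$, exchangeable
domains, no clipping.

Choices worth making explicit:

* **Scores are unbounded by default** (`clip_mode = "none"`). The power
  assumptions live on an unbounded normal scale (SD 4 around a mean of
  4–6), and clipping to [0, 10] would bias the moments the
  parameter-recovery and coverage tests target. `clip_mode = "truncate"`
  exists for realistic-looking demonstration data and is documented as
  biasing.
* **Domains are exchangeable by default** (`domain_effects = NULL`). The
  sample-size model assumed a common intervention effect across domains;
  heterogeneous per-domain offsets (as real data show) are available as an
  optional zero-sum vector.
* **Keyword-level realization** (`realize_keywords()`) converts a target
  score into a presence vector by greedy largest-weight-first selection,
  never overshooting and undershooting by at most $10\,w_{max}/\sum w$ —
  the rubric's resolution. This makes keyword-level pipelines (consensus,
  rescoring, weight sensitivity) runnable end to end without manuscripts.
* **Weight-sensitivity schemes.** The original study varied its weighting
  systems; the exact schemes are not reproduced here, so
  `weight_sensitivity()` implements two declared ones — uniform integers
  1..5 and a symmetric Dirichlet scaled to the rubric size — plus an
  identity scheme as a degenerate reference, and names the scheme in its
  output.

What the generator deliberately does **not** emulate: non-normal score
distributions, rater disagreement processes, floor/ceiling effects of real
rubrics, and domain-specific effect heterogeneity unless requested. Passing
tests therefore validate the estimators under the design's stated
assumptions, not the behaviour of human raters or real manuscripts.

## Numerical and degenerate-input conventions

* Zero variance of the paired differences (all $d_p$ identical) is an
  error, not a silent $p = 1$: no finite-variance inference exists there.
* Variance-component truncation at zero is flagged, never silent.
* `essential_score()` returns `NA`, not 0, when no essential keywords
  exist; the CSV serialization writes an empty field.
* Greedy keyword selection breaks weight ties in rubric order, making
  realizations reproducible.
* Seeds: every stochastic function takes an explicit seed and restores the
  caller's RNG state; `NULL` means "use the ambient stream", which is what
  replicate loops need.

## Problem sizes used in validation

The test suite validates moments and correlations on single trials of
2,000 participants; type-I error, power and CI coverage on 5,000 Monte
Carlo replicates at the study size ($N = 40$); estimator equivalence
against REML on 200 simulated trials; and the scoring and realization
rules on 1,000 randomly drawn rubrics each. The narrative drivers under
`analysis/` use 1,000 replicates for a faster end-to-end run and state so
in their output files.

## Known limitations

The rubric files shipped under `inst/extdata/` are synthetic illustrations,
not the original study's rubrics, which are not public in usable form. The
per-domain t-tests ignore the (mild) dependence induced by shared
participants across domains, exactly as the original analysis strategy
does. The ancillary comparison assumes every (protocol, domain) pair has a
published score; it refuses, rather than imputes, when one is missing.
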