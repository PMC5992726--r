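---
title: "Calling and imputing cytosine methylation with a distance-aware HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and imputing cytosine methylation with a distance-aware HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylHMM)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) measures DNA methylation one
cytosine at a time: unmethylated cytosines are converted to thymines, so the
ratio of C to C+T reads at a position estimates its methylation level.  Two
practical problems limit naive per-site callers.  First, coverage is uneven:
a large fraction of cytosines receive zero, one or two reads, where a
binomial test is either impossible or severely underpowered, leaving the
methylome riddled with holes.  Second, the bisulfite reaction is imperfect
(roughly 1% of unmethylated cytosines fail to convert), so raw levels are
biased unless the conversion rate is known.

`methylHMM` addresses both by borrowing strength from neighbouring
cytosines.  Methylation is strongly autocorrelated along the genome over
tens of base pairs, so even an uncovered cytosine carries information
through its neighbours.  The package fits a hidden Markov model along the
cytosine sequence and returns, for *every* cytosine in the genome, a
posterior probability of being methylated, a status call, and a
recalibrated methylation level — plus an estimate of the conversion rate as
a by-product.

## The model

Each cytosine $t$ has a hidden state $i_t \in \{U, M\}$ (unmethylated,
methylated).  Given the state, the observed methylated count $m_t$ out of
$r_t$ total reads is binomial,

$$B(m_t, r_t, p_{i c_t}) = \binom{r_t}{m_t} p_{i c_t}^{m_t}
  (1 - p_{i c_t})^{r_t - m_t},$$

with a success probability $p_{ic}$ specific to the state and the sequence
context $c_t$ of the cytosine.  Six contexts are distinguished, defined by
the two bases 3' of the cytosine on its own strand: CG, CCG, CWG, CAA, CTA
and the pooled remainder of CHH (written `CHH_rest`; H = A/C/T, W = A/T,
Y = C/T).  These sub-classes of the classical CG/CHG/CHH scheme have
distinct methylation propensities in plants; a 3-context mode is available
when no reference genome is at hand and contexts must be taken from the
CGmap file.  An uncovered cytosine ($r_t = 0$) has emission probability 1
in both states: it carries no direct information, and its posterior is
determined entirely by its neighbours — this is how imputation happens.

Because cytosines are unevenly spaced, the transition matrix between
consecutive cytosines depends on their genomic distance $d$:

$$A(d) = A^0\, e^{-d/D} + \tfrac{1}{N}\left(1 - e^{-d/D}\right),
  \qquad N = 2.$$

At $d = 0$ the zero-distance matrix $A^0$ applies; as $d \to \infty$ all
transitions become equally likely, so distant cytosines are a priori
independent.  Both $A^0$ and the decay length $D$ are specific to the
*transition context*, the ordered pair $(c_t, c_{t+1})$ — $6^2 = 36$
matrices and decay lengths in the default mode.

Two interpretable quantities fall out of the fit:

* $1 - p_{U,\mathrm{CG}}$ is the bisulfite conversion rate (the probability
  that a truly unmethylated cytosine reads as unmethylated).  CG is used
  because non-CG methylation is maintained more "fuzzily" and would bias
  the estimate.
* $1 - p_{M,\mathrm{CG}}$ bounds the inappropriate conversion of methylated
  cytosines from above; it is confounded with cellular heterogeneity in the
  sample, hence reported as an upper bound only.

The per-site output is the posterior $\gamma_{it}$, the status call
$\arg\max_i \gamma_{it}$, and the recalibrated level

$$m'_t = p_{U,c_t}\,\gamma_{U,t} + p_{M,c_t}\,\gamma_{M,t},$$

which is defined at every cytosine (covered or not), always lies in
$[p_{U,c}, p_{M,c}]$, and corrects for conversion failure because the
baseline $p_U$ absorbs it.

## Estimation

**Decay lengths first.**  $D$ is not estimated inside EM.  Before fitting,
`estimate_decay()` computes the Pearson correlation of raw levels $m/r$
between *adjacent* covered cytosines (no other cytosine in between, within
one chromosome), per transition context and distance, and fits
$y(d) = a_0 e^{-d/D}$ by Levenberg–Marquardt nonlinear least squares
(`minpack.lm`).  Starting values are $a_0 = y(d_{\min})$ and a multi-start
over $D \in \{5, 30, 100\}$ bp, keeping the best fit; $D$ is clamped to
$[1, 1000]$ bp.  Transition contexts with fewer than 3 usable distances (or
a failed optimization) inherit a pooled fit over all contexts.  Defaults
`max_distance = 100` bp and `min_pairs = 100` reflect that the empirical
autocorrelation decays within a few tens of bp, so 100 bp spans the signal,
and that a Pearson correlation on fewer than 100 pairs is too noisy to help
the fit.  Correlating raw levels (coverage $\ge 1$, unweighted) is a
deliberate choice: levels are the only per-site quantity available before
the model exists.

**Modified Baum–Welch.**  With $D$ fixed, `methylHMM()` runs EM.  The
E-step is the scaled forward–backward recursion (per-position scaling
constants rather than log-space; the choice is internal and is pinned by an
exhaustive path-enumeration oracle in the test suite).  Each chromosome is
an independent chain started from $\pi$.  The M-step differs from the
classical algorithm because $A^0$ enters the likelihood only through
$A(d)$: the update weights each pairwise posterior $\xi_{ijt}$ by
$(A^0_{ij}/A_{ij}(d_t))\, e^{-d_t/D}$ — the last factor being
$\partial A_{ij}/\partial A^0_{ij}$ — sums within each transition context,
and renormalizes rows (the stationarity condition of the expected
complete-data log-likelihood under the row-sum constraint).  At $d = 0$
this reduces to the classical update.  The emission update is the
posterior-weighted pooled methylated fraction per state and context;
$\pi$ is re-estimated from the chain-start posteriors.

Numerical choices: the binomial coefficient is kept in the emissions (it
cancels in all posteriors and updates, but makes the reported log-likelihood
the true data log-likelihood, which the monotonicity contract needs);
emission probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ so emissions
stay positive; a log-likelihood decrease beyond $10^{-8}$ raises an error
rather than being silently tolerated.  Convergence is declared at an
absolute log-likelihood change below `tol = 1e-4` (default), with
`max_iter = 500`; when the iteration cap ends on an M-step, one extra
E-step realigns the reported posteriors with the reported parameters.

**Initialization and labels.**  EM starts from $p_U = 0.05$, $p_M = 0.80$
in every context, $A^0$ diagonally dominant at 0.9, and uniform $\pi$,
breaking the label symmetry toward the conventional meaning of U and M.
Because the likelihood is invariant under relabelling, the fit enforces
$\overline{p_U} \le \overline{p_M}$ after convergence by swapping labels if
necessary.  Ties in the posterior argmax go to U, conservative toward the
unmethylated background.

**Chain topology.**  Both strands are interleaved on one coordinate axis
sorted by position; the distance is the position difference regardless of
strand (a palindromic CG pair on opposite strands is 1 bp apart).
Transitions never cross a chromosome boundary.  Cytosines whose context is
undefined (N bases, chromosome ends) are retained in all outputs for
bookkeeping but excluded from fitting and summaries; they are reported with
`NA` posteriors rather than being forced into one of the six classes.

## The baseline caller

For benchmarking, `baseline_calls()` implements the conventional approach:
an exact one-sided binomial test against an error rate (default 0.01,
i.e. a typical 0.99 conversion rate; optionally the HMM's own estimate) at
informative sites ($r \ge 3$), Benjamini–Hochberg corrected at
$\alpha = 0.05$ by default (the correction and sidedness are configurable,
as conventions differ), and majority-vote imputation for $r < 3$ sites from
directly-called sites of the same context within a 200 bp neighbourhood
(interpreted as $\pm 100$ bp around the focal site, boundaries inclusive;
neighbours are context-matched but not strand-matched).  Ties and isolated
sites stay `undefined`, and undefined calls count as false negatives in F1
evaluation.

## What the simulator emulates — and what it does not

`simulate_methylome()` draws from the model's own generative process:
i.i.d. contexts with the composition of a uniform-random genome (a quarter
of cytosines CG), geometric inter-cytosine gaps with mean 5 bp (the density
of a cytosine-rich plant genome), hidden states from the distance-dependent
chain, Poisson coverage (default $\lambda = 6$, naturally including
zero-coverage mass), and binomial counts.  Default truth parameters are
$p_U = 0.01$ (1% conversion failure), $p_M$ decreasing from 0.80 (CG) to
0.30 (pooled CHH) to reflect the context ordering seen in plant methylomes,
$A^0$ diagonal 0.9, $D = 30$ bp.  These are synthetic defaults, not values
fitted to any dataset.

Passing tests on these simulations demonstrates correctness of the
machinery (E/M-steps, imputation, saturation behaviour), *not* real-data
performance: the simulator draws states from the very Markov family the
model assumes, contexts independently of position, and coverage without
mappability or GC structure.  Real methylomes violate all three (e.g. CG
islands, TE clustering, cellular heterogeneity making $p_M$ effectively
site-variable), which is precisely why $1 - p_M$ is only an upper bound.

## Evaluation suite

* `downsample()` thins counts binomially per read class, matching
  read-level Bernoulli sampling in distribution (the package consumes
  counts, not alignments).
* `saturation_analysis()` refits at retention fractions (default 0.9, 0.5,
  0.25, 0.1), reusing the full-data decay constants, and scores F1 against
  the full-data calls of the same method; overall F1 is the
  truth-frequency-weighted mean of per-state F1.
* Genome-wide summaries: GML from calls (#mC / all C), naive wGML
  ($\sum m_t / \sum r_t$) and recalibrated wGML
  ($\sum m'_t r_t / \sum r_t$), per context.  On simulations the two wGMLs
  are stable under 10× thinning while the call-based GML collapses in
  low-$p_M$ contexts — the motivation for the recalibrated level.
* `confidence_summary()` reports high-confidence fractions (max posterior
  $\ge 0.9$) by coverage category: imputed ($r=0$), uninformative
  ($r \in \{1,2\}$), informative ($r \ge 3$).
* `enrichment_profile()` computes meta-feature profiles of $m'$ (scaled
  body, default 20 bins; fixed 1 kb flanks in 10 bins; minus-strand
  features flipped; sites in overlapping features counted once per
  occurrence).

## Problem sizes and reproducibility

The test suite and the acceptance script regenerate everything from seeds:
oracle equivalence on 100 random chains of length $\le 10$ against
exhaustive path enumeration; EM monotonicity on 100 simulated datasets of
2,000 sites; parameter recovery on 200,000 sites at Poisson(6) coverage;
saturation and wGML robustness on 60,000- and 30,000-site methylomes at
20× coverage.  These sizes give Monte-Carlo error comfortably below the
assertion tolerances while keeping a full run in the low minutes on one
core.  The forward–backward kernel is C++ (Rcpp), as is usual for HMM
packages in this field; all surrounding logic is plain R.

## Known limitations

* Two states only: intermediate methylation (common at CHG/CHH in plants,
  or in heterogeneous tissue) is absorbed into $p_M$ rather than modelled
  as a third state.
* $D$ is plug-in, not jointly estimated; a misspecified decay length
  biases posteriors for sparsely covered regions (the clamp to
  $[1, 1000]$ bp bounds the damage).
* Whether strands should be interleaved or fitted separately is a genuine
  modelling choice; interleaving is used because methylation of the two
  strands of a CG dyad is strongly coupled.
* Conversion-rate estimates inherit any contamination of the U population
  (e.g. mis-mapped reads) directly into $p_U$.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_methylome(n = 20000, lambda = 6, seed = 1)
fit <- methylHMM(sim$methylome)
fit                       # parameters, conversion rates
summary(fit)              # + coverage categories, confidence, GML
head(predict(fit, type = "level"))
f1_scores(fit$status, sim$states)$overall
```
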