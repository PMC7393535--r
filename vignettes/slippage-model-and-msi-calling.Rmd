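---
title: "A multinomial slippage model for tumor-only MSI calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multinomial slippage model for tumor-only MSI calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slipmsi)
```

## The problem

Microsatellite instability (MSI) marks mismatch-repair-deficient tumors and
guides immunotherapy, but most sequencing-based MSI callers need a matched
normal sample, which is unavailable for leukemias, FFPE archives and
xenografts. `slipmsi` scores MSI from a single tumor BAM by modelling the
physical process that generates microsatellite variation — polymerase
slippage during replication — and comparing each tumor's per-site slippage
rate against a panel-of-normals baseline.

## The slippage model

Copying one repeat unit of a microsatellite has three outcomes: the
polymerase slips back and the unit is lost (probability $p$, "hysteresis
synthesis"), the unit is copied faithfully ($1-p-q$), or an extra unit is
gained ($q$, "pre-synthesis"). Treating the $n$ reference units as
independent draws, the observed tract length $y$ at a site with $n$
reference copies has probability

$$
\Pr(y) =
\begin{cases}
\binom{n}{\,n-y\,} (1-p-q)^{y}\, p^{\,n-y} & y \le n \\[4pt]
\binom{n}{\,y-n\,} (1-p-q)^{2n-y}\, q^{\,y-n} & n < y \le 2n
\end{cases}
$$

counting only minimal-step paths. Paths that reach $y$ with extra
back-and-forth steps carry negligible mass and are dropped, so the pmf sums
to $(1-q)^n + (1-p)^n - (1-p-q)^n$, slightly below one; the forward
simulator renormalises over the support $0..2n$ so draws form a proper
distribution (whether to renormalise was an open choice — without it the
simulator would need an explicit "no event" escape, and renormalisation
keeps matched-size Kolmogorov–Smirnov comparisons coherent). Given $m$
spanning reads $y_1..y_m$ the rates have closed-form estimates

$$
\hat p = \frac{\sum_{y_i \le n} (n - y_i)}{n\,m}, \qquad
\hat q = \frac{\sum_{y_i > n} (y_i - n)}{n\,m}.
$$

The summation ranges follow the two branches of the pmf: the deletion sum
runs over reads at or below the reference length, the insertion sum over
reads above it. These are not the exact maximum-likelihood estimates of the
renormalised pmf — a small downward bias of order $1 - (1-q)^{n-1}$ remains
(about 0.003 at $n=15$, $p=0.05$, $q=0.01$) — but the acceptance suite
verifies the log-likelihood surface peaks within half a lattice step
(0.005) of $(\hat p, \hat q)$, and estimator recovery on simulated data is
well inside 0.01 mean absolute error at $m = 5000$.

Deletion slippage $\hat p$ is the MSI signal; insertion slippage $\hat q$
does not separate MSI from MSS samples and is carried only as a model
parameter. `ks_fitness()` checks model adequacy per site by a two-sample
Kolmogorov–Smirnov test between observed lengths and a matched-size
simulation at $(\hat p, \hat q)$; a site is "fitted" when the test does not
reject at $\alpha = 0.05$. On heavily tied integer data the asymptotic KS
p-value is conservative, so the observed self-fitness rate (about 99–100%
of model-simulated sites) sits above the nominal 95%.

## From reads to repeat lengths

The scanner (`scan_reference()`) reports every maximal tandem repeat of a
primitive 1–5 bp motif, with minimum copy numbers of 5 for homopolymers and
3 for longer motifs — configurable defaults chosen to match common MSI
panel scanners, since no published threshold exists for this step.
Coordinates are 0-based internally and 1-based in TSVs.

`extract_all()` counts whole motif copies per read. Because aligners place
indels ambiguously inside repeats, the default path re-locates the tract by
exact match of the `anchor` (5 bp) flanking sequence on both sides and
counts consecutive motif copies between the anchors; reads whose flanks
cannot be found exactly within one tract length of the expected position
are discarded, as are anchor hits whose implied tract starts with non-motif
sequence (a mutated-flank signature). A CIGAR-walking fallback
(`method = "cigar"`) is provided and tested to agree with flank
re-anchoring on error-free reads; it attributes boundary insertions to the
tract because left- and right-aligned indel conventions both place tract
indels on a boundary. Reads must be primary, non-duplicate, MAPQ ≥ 20, and
span tract plus anchors. No base-quality filter is applied.

## Baseline and calling

`build_baseline()` summarises $\hat p$ per site across a panel of normals:
a site is kept when its coverage exceeds 20 reads in strictly more than
half of the panel, and $\mu_i$, $\sigma_i$ are computed over exactly the
coverage-passing samples (which samples enter $\mu,\sigma$ was an open
choice; restricting to coverage-passing samples keeps low-coverage noise
out of the reference spread). $\sigma$ uses the population formula
(divide by $k$) because the panel is treated as the reference population;
`sd_type = "sample"` switches to $k-1$. A tumor site with
$\hat p > \mu_i + 3\sigma_i$ (strict) is unstable, and the MSI score is the
percentage of unstable sites among covered sites ($m > 20$, mirroring the
baseline rule). The binary MSI/MSS label uses a 10% score cutoff — a
reporting convention only, exposed and echoed in the output header; the
score itself and its sample ranking are the primary result. Baselines embed
an MD5 hash of the site list and calling refuses a mismatched hash, so a
baseline can never silently be applied across panels.

## Discriminative sites and cohort evaluation

`site_auc_table()` ranks sites by how well $\hat p$ separates labelled MSI
from MSS samples, using the mid-rank Mann–Whitney AUC (ties count one
half); sites lacking covered samples in either class are skipped rather
than scored 0.5. `select_dms()` keeps sites with AUC strictly above the
threshold. The default is 0.65, with 0.75 exposed for selecting only
strongly discriminative sites — both thresholds appear in the method's
source literature and the choice between them is not decidable from it.
`evaluate_cohort()` applies the same AUC estimator to sample-level MSI
scores. An optional `split` column in the labels confines selection to
discovery samples so held-out test samples cannot leak into the panel.

## What the synthetic cohorts emulate

The fixture generator plants maximal microsatellites (60% homopolymers of
8–20 copies, the rest 2–5 bp motifs) in non-repetitive spacer sequence,
assigns each site a normal-state deletion rate rising linearly from 0.001
to 0.05 with repeat count (20% jitter; $q = p/5$, matching the observation
that deletions dominate insertions), and simulates spanning reads at
Poisson coverage (mean 50). MSI samples elevate $p$ five-fold at 30% of
sites (clamped to $p + q \le 0.9$); tumor purity mixes tumor- and
normal-parameter reads binomially. Spacers are constrained so no scannable
repeat can arise by chance, and every assembled chromosome is re-verified
against the scanner, making truth-list recovery exact by construction.
Reads are error-free with correct CIGARs: the fixtures test measurement
and model logic, not robustness to sequencing noise, mapping error or
interrupted repeats — passing tests say nothing about those real-data
features. Problem sizes used throughout the test and acceptance runs (500
sites, 20 samples per role, 3–50 seeds per experiment) were chosen as the
smallest cohorts at which the Monte-Carlo assertions are stable.

On these defaults the pipeline separates 20 MSI from 20 MSS samples with
cohort AUC 1.0 and mean scores near 30% (MSI) versus 1–2% (MSS). Because
reads are error-free and the effect is strong, the AUC stays saturated
down to mean coverage 5 when the detection floor is lowered to $m > 0$
(with the default floor of 20 a 5× sample has no covered sites and no
defined score); the depth experiment therefore asserts that the
seed-averaged AUC never *increases* as depth falls. Mean MSI score rises
monotonically with tumor purity across 0.05–1.0.

## Numerical choices and limitations

Binomial coefficients are evaluated in log-space (`lchoose`), keeping the
pmf exact to ~1e-15 of its closed-form mass up to $n$ of at least 50.
Estimates are clamped to $[0, 1]$; reads with $y > 2n$ (impossible under
the model, possible in noisy data) still contribute inserted units to
$\hat q$ but carry zero likelihood. Degenerate KS inputs (identical
single-valued samples) are declared fitted with statistic 0. The model
ignores motif-dependent slippage rates, interrupted and compound repeats,
multi-pass slippage paths, and sequencing error; matched tumor–normal
calling and purity-aware correction are out of scope.
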