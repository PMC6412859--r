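---
title: "From two-color miRNA arrays to a target hub network: methods and design"
author: "mirTarNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From two-color miRNA arrays to a target hub network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirTarNet)
```

# The problem

Small transcriptomic studies of miRNA regulation often share one design:
a handful of two-color miRNA microarrays establishes which miRNAs change
between two conditions, qRT-PCR validates those calls sample by sample,
public miRNA–target interaction (MTI) databases propose the genes those
miRNAs repress, and the targets regulated by several altered miRNAs at
once — the *hubs* of the bipartite miRNA–target network — are singled
out and validated at the mRNA level. The motivating application is a rat
model of capsaicin-induced sensory neuropathy, where six down-regulated
cardiac miRNAs converge on four hub targets (*IGF-1*, *SLC2a-12*,
*EIF-4e*, *ULK-2*), each predicted — and then measured — to be
up-regulated.

mirTarNet implements that whole chain as tested, reusable functions,
together with synthetic-data generators that plant known effects at
every stage so the pipeline's recovery behaviour can be quantified.

# Array preprocessing

## Normexp background correction

Observed foreground intensity is modelled as $X = B + S$ with
$B \sim N(\mu, \sigma^2)$ optical/chemical background and
$S \sim \mathrm{Exp}(\alpha)$ true signal (mean $\alpha$, across
probes). The corrected intensity is the posterior mean

$$E[S \mid X = x] = \mu_s + \sigma\,
  \frac{\phi(\mu_s/\sigma)}{\Phi(\mu_s/\sigma)},
  \qquad \mu_s = x - \mu - \sigma^2/\alpha,$$

plus an offset (default 10) that keeps weak-spot log ratios stable. The
Mills ratio is evaluated in log space, so the correction stays positive
and strictly monotone arbitrarily far below the background mean; the
test suite checks it against direct numerical integration of the
posterior to $10^{-6}$ and against an independent implementation.

Parameters are estimated per array and channel by the method of moments:
the exponential component owns all the skewness, so
$\hat\alpha = (m_3/2)^{1/3}$ from the third central moment, then
$\hat\sigma^2 = s^2 - \hat\alpha^2$ and $\hat\mu = \bar x - \hat\alpha$.
Two numerical points matter in practice:

* On signal-dominated arrays ($\alpha \gg \sigma$) the background
  variance is a tiny difference of large numbers and is *not* reliably
  identifiable from moments; the estimator then takes the boundary
  solution ($\hat\sigma^2 = 0.01\,s^2$), which leaves the correction of
  bright spots essentially unchanged. A warning is raised only when the
  moments are inconsistent beyond what that regime explains.
* `normexpFit(x, method = "mle")` refines the moment estimates by
  maximizing the exact convolution likelihood; it recovers all three
  parameters even in the signal-dominated regime and is the right choice
  when the background estimate itself is of interest.

## Global lowess MA normalization

Per array, $M = \log_2(\text{sample}/\text{reference})$ is regressed on
$A$ (mean log2 intensity) with `stats::lowess` — locally weighted linear
regression with tricube weights, span 0.3 and 3 robustness iterations —
and the fit is subtracted. The span default suits arrays of a few
hundred to a few thousand probes; no span is canonical in the
literature, so it is exposed as a parameter. Degenerate input (all $A$
equal) falls back to centering $M$, with a warning. Normalization is
exactly idempotent on trends the local-linear smoother reproduces and
approximately idempotent otherwise; because lowess is not a projection,
a second pass on noisy data moves points by a small fraction (observed
under 10%) of the removed bias, not by zero.

## Differential-expression calling

The design is a common-reference one: every array hybridizes one pooled
sample (Hy3) against the same pooled reference RNA (Hy5). With $n$
arrays per group the pipeline forms all $n^2$ cross-group pairs of
normalized log ratios — the "individual parallel comparisons" — whose
mean and SD are each probe's effect size, while the p-value comes from a
Welch unequal-variance t-test of the normalized per-array log ratios
grouped by condition. With 2 arrays per group the effect is the mean of
4 pairwise log2 ratios and the test is 2 vs 2; both summaries are
reported per probe.

Selection uses the joint rule: `significant` needs $p < 0.05$ **and**
$|\bar M| > 0.6$ ($2^{0.6} \approx 1.5$-fold); `candidate` passes the
magnitude cut only (a missing p-value caps the tier there); everything
else is `not_selected`. No multiple-testing correction is applied — the
workflow treats the array as a screen whose calls are individually
re-tested by qRT-PCR, which is where error control actually happens.

Probes must exceed the 5th percentile of corrected foreground on at
least half the arrays to be tested; the percentile is configurable and
the resulting "detectable" count is a property of data and rule, not of
the method.

# qRT-PCR quantification

* **miRNA assays** are summarized per group on raw Cp by default: one
  cycle is one doubling, so
  $\widehat{\Delta\log_2} = -(\overline{Cp}_\text{neuropathy} -
  \overline{Cp}_\text{control})$, with a Welch test on per-sample Cp and
  the signed fold change $\mathrm{sign}(L)\,2^{|L|}$. A reference-assay
  mode (per-sample $\Delta$Cp) is available. An assay needs
  amplification in at least 2 samples per group before the 45-cycle
  ceiling to count as detected; otherwise it is reported "n.d.".
* **Abundance classes** subtract the mean Cp of an abundant reference
  miRNA (miR-1 in the cardiac application): $\Delta < 6$ is high,
  $\Delta > 10$ low, the boundary values inclusive are intermediate
  (strict inequalities, as conventionally printed).
* **mRNA targets** use the classical $2^{-\Delta\Delta Cp}$ method
  normalized to a housekeeping gene, calibrated to the arithmetic mean
  control $\Delta$Cp (so the control geometric-mean level is exactly 1;
  group ratios are computed on group-mean $\Delta$Cp). The group test
  runs on per-sample levels by default, or on $\Delta$Cp by choice —
  both are defensible and published tables rarely say which was used.
  `efficiencyCorrectedLevel()` generalizes base 2 to per-assay
  amplification efficiencies $E \in (1, 2]$ in the Pfaffl style.

**Reconciliation** gives qRT-PCR primacy: a confirmed call needs a
detected, significant, direction-concordant qRT-PCR result; a detected
significant discordant result overrules the array direction; a
non-significant result leaves the array call standing, unconfirmed and
flagged; an undetected assay yields "n.d." with the array call standing.
On the bundled example tables this yields 7 final-down, 1 final-up and
6 of 8 confirmed.

# MTI integration and the hub network

Three source dialects mirror the public database landscape: a
confidence-scored prediction set (higher is better), a
regression-scored prediction set (more negative is stronger) and a
validated set (no score required). Poor predictions are removed with
strict boundaries: confidence scores $\le 80.0$ and regression scores
$\ge -1.2$ are dropped; validated records are exempt. The network is the
**union** over sources, one edge per distinct (miRNA, target) pair with
the supporting sources kept as provenance; miRNA matching is
case-insensitive with mature-arm suffixes significant.

A hub is a target with at least `minDegree` (default 3) distinct
regulating miRNAs — degree counts miRNAs, not supporting records. Since
miRNAs repress, a hub whose regulators are unanimously down-regulated is
predicted up-regulated and vice versa; mixed regulator sets are
`ambiguous` under the default unanimity rule (a majority rule with a
configurable fraction exists, but unanimity is the only case the
motivating data exercise). Exports (node/edge TSV, SIF, GraphML) are
deterministic and round-trip exactly.

# The synthetic-data generators

The generators define the study conditions under which the pipeline's
recovery claims are made:

* **Arrays** (`simulateArrays`): 300 probes, 2 arrays per group. Each
  probe's baseline signal is exponential with mean 1000 across probes
  (so the marginal intensity model matches what normexp assumes) on top
  of $N(50, 5^2)$ background; per-channel log-normal measurement noise
  is 0.10 log2 units for the sample channel and 0.05 for the common
  reference; planted log2 effects default to the eight example values
  (−1.95 … +0.75). Planted probes draw their baseline from above the
  30th percentile of the signal distribution — a differential call on a
  spot at background level is not meaningful. Dye bias is a smooth
  sinusoid-plus-trend of the spot's realized abundance, amplitude 0.4
  log2 units — comparable to the effects being recovered, so skipping
  normalization leaves a visible M-vs-A trend.
* **Ct tables** (`simulateCt`): 6 samples per group,
  $Cp = \text{baseline} - \text{effect} \cdot 1_\text{neuropathy} +
  \text{shift}_s + \varepsilon$, technical SD 0.2 cycles for miRNA
  assays and 0.15 for the mRNA panel, an optional per-sample loading
  shift (SD 0.5) that reference normalization must remove, and a
  45-cycle ceiling beyond which values are undetermined (one assay's
  baseline of 46 reproduces the "n.d." case). Biological and technical
  variation are folded into one homoscedastic SD; the data motivating
  the defaults provide no variance decomposition to justify more.
* **MTI tables** (`simulateMti`): planted hubs receive threshold-passing
  interactions spread across the dialects; decoys receive either
  low-degree passing interactions or score-failing ones, so hub recovery
  is exact by construction whenever the filters behave correctly — which
  is precisely what the test measures.

What these generators do *not* emulate: probe sequence effects and
cross-hybridization, spatial artifacts, heteroscedastic Cp noise near
the detection limit, and the correlation structure of real MTI
databases. Passing recovery tests therefore demonstrates the
correctness of the computational chain under its own model assumptions,
not performance on real arrays.

A note on what recovery can promise: two of the eight planted effects
(0.63 and 0.75) sit essentially on the 0.6 selection threshold. With
realistic array noise the 0.63 effect lands below the cut in roughly a
third of simulations — as marginal effects do in real screens — so the
guaranteed claims are direction recovery (8/8), magnitude accuracy
(median absolute error < 0.3 log2) and a clean null (no unplanted probe
crossing 0.6), while threshold-crossing is only guaranteed for effects
clearly above the cut.

# Numerical and design choices

* Zero-variance Welch inputs take the convention $p = 1$ for equal
  means, $p = 0$ otherwise, with a warning; p-values always use the
  exact t distribution (group sizes here are 2–6).
* $\log_2$ ratio 0 maps to fold change $+1$ (no change), keeping the
  signed transform odd and continuous in meaning.
* All numeric columns are rounded (2 decimals) only at serialization;
  full precision is kept internally.
* Every generator is a pure function of its argument list including the
  seed, restoring the caller's RNG state; identical configurations give
  byte-identical output files, and each stage file carries a hash of the
  configuration in a header comment.
* Problem sizes in the tests (300 probes, 2 arrays/group, 6 samples per
  group, 200 decoy targets, 10,000-replicate type-I-error simulation)
  are the defaults of the generators and chosen to match the design the
  workflow emulates while keeping the whole suite quick to run.

# Known limitations

* The Welch test on 2 vs 2 arrays has minimal power; the `candidate`
  tier exists precisely because a magnitude-only screen followed by
  qRT-PCR is the intended use.
* Moment-based normexp estimation cannot resolve the background SD on
  signal-dominated arrays (see above); use the MLE flag if that quantity
  matters.
* Species tags on MTI records are carried but not enforced by default;
  a strict mode can be layered on by pre-filtering records.
* The step from "15 hubs" to a handful of biologically chosen genes in
  the motivating study is human judgment; the package represents it
  only as a configurable annotation gene list.

# A complete run

```{r, eval = FALSE}
cfg <- defaultRunConfig(seed = 1, outDir = "run1")
rep <- runPipeline(cfg)
rep$counts
rep$hubs
rep$concordance
```

The report lists probes tested, selections, confirmations, final
directions, edge and hub counts, and per-hub concordance between the
predicted direction and the measured mRNA change; every count equals a
recount from the stage files the run wrote.
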