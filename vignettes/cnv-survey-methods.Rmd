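---
title: "Methods: CNV calling from array CGH and read depth"
author: "cghcnv maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV calling from array CGH and read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cghcnv)
```

# The problem

Copy number variants (CNVs) — deletions and duplications longer than about
1 kb — are hard to call reliably from any single platform. Array CGH reports
a log2 test/reference intensity ratio per probe segment, but segmentation
output is contaminated by false positives; read-depth analysis of short-read
sequencing scales with copy number but is distorted by GC bias and repeats;
and any design that hybridizes every animal against one shared reference
animal confounds test-animal CNVs with CNVs carried by the reference (the
"reference effect"). `cghcnv` implements a survey pipeline that combines
these signals: a trio-trained logistic classifier for array segment calls,
chromosome-aware filters, merging into CNV regions (CNVRs), a constrained
mixture model for read-depth copy number, cross-platform verification, and
spatial/gene-overlap statistics — all exercisable end to end on synthetic
data with known truth.

# The segment-call classifier

Training labels come from the experimental design rather than thresholds:

* **Known positives** — a progeny call matching a parent call at the *same
  first and last probe index* (hence identical coordinates) is an inherited,
  real CNV (`validate_trios()`).
* **Known false positives** — every call from a self-self hybridization
  (the reference sample against itself) is an artifact by construction.

A forward stepwise logistic regression (`stepwise_fit()`) searches main
effects — |log2 ratio| (absl2r), a deletion indicator, length, ln(length),
ln(ln(length)), length², probe count, ln(probes), ln(ln(probes)), probes² —
plus two- and three-way interactions among selected main effects. Terms
enter at Wald chi-square p ≤ 0.3 and stay while p ≤ 0.35. The fixed
survey model shipped as `published_model()` is

$$\mathrm{logit}(p) = -0.19 + 29.51\,\mathrm{absl2r}
  - 4.91 \ln(\ln(\mathrm{length})) + 8.24 \ln(\ln(\mathrm{datapoints}))$$

with acceptance threshold $p \ge 0.95$, selected by leave-one-out
crossvalidation over the grid {0.5, 0.6, 0.7, 0.8, 0.9, 0.95, 0.96, 0.97,
0.98, 0.99} (`loo_crossvalidate()`; per-fold refits keep the selected term
set fixed, mirroring the behaviour of the classical crossvalidation
procedure the survey used).

Numerical choices worth knowing:

* **Double-log domain.** ln(ln(x)) requires x > 1. Calls with one probe or
  length ≤ 1 get p = 0 in batch mode (downstream filters require ≥ 3 probes
  anyway); `strict = TRUE` raises an error instead.
* **Separation and the Hauck–Donner effect.** Near-perfect separation
  deflates Wald statistics, which would silently *hide* the strongest
  predictors from a Wald-driven search. A candidate whose trial fit is
  (near-)separated therefore enters as maximally significant, and a
  separated final fit is re-estimated with a light ridge penalty, with a
  warning.
* **Collinear transforms.** Over realistic call lengths (1 kb–200 kb),
  ln(length) and ln(ln(length)) correlate beyond 0.999. A greedy search can
  pick either proxy; what is identifiable is the *functional* model, not
  the specific transform. Our generative-recovery tests assert functional
  recovery (held-out predictions, sign pattern on the restricted candidate
  set) rather than exact term identity.

# Filters

Pre-model: calls with absl2r < 0.1 are dropped; arrays whose probe-ratio
variance exceeds median + 3·MAD across animals are treated as failed
hybridizations (the outlier rule is our choice; only the intent —
"larger variation than the other animals" — is given). Post-model,
autosomal calls must reach p ≥ 0.95, length ≥ 1 kb, ≥ 3 probes and
absl2r ≥ 0.25 (all inclusive). On chromosome X the same filters apply,
then males keep only duplications: a male deletion against a female
reference may only reflect X dosage. On the virtual "unknown" chromosome
(unplaced scaffolds joined with 100-bp N spacers), a call must sit inside
one scaffold, leave ≥ 2 scaffold probes outside itself, span ≥ 2 probes,
and exceed absl2r 0.32 — strictly, because that bound was set from
observed self-self calls at exactly −0.32.

# CNV regions and spatial structure

Calls from all animals within 1,500 bp of one another merge transitively
into CNVRs (`merge_to_cnvrs()`; gap semantics `next.start − prev.stop ≤
1500`, consistent with surviving neighbours being ~1.5 kb apart). CNVRs
observed in *every* animal are flagged as putative reference-animal CNVs.

Spatial clustering is tested by comparing observed inter-CNVR distances
(adjacent gaps within chromosomes; cross-chromosome pairs excluded — the
procedure's scope here was genuinely open and per-chromosome is the
defensible reading) against one size-matched uniform placement
(`simulate_uniform_null()`: observed lengths kept, chromosomes assigned
length-proportionally, ≥ 1,500 bp spacing, rejection sampling) via a
two-sample Kolmogorov–Smirnov test.

**A calibration caveat we verified and preserve.** Inter-CNVR distances of
a uniformly placed set are order-statistic spacings: they are negatively
correlated through the chromosome-length constraint, so their empirical CDF
fluctuates *less* than an iid sample's. `ks.test` computes p-values under
an iid null, making this test conservative — in 200-replicate experiments
the null rejection rate at 0.05 is ~0.5%, not 5% (two samples of
`diff(sort(runif(n)))` reproduce this without any package code). The
consequence cuts one way only: clustering found significant by this test is
*at least* as significant as reported. Power is unaffected in practice —
planted 2-kb clustering at 200 CNVRs yields p ≪ 0.01.

# Read-depth copy number

Per-base depth (bedGraph in, run-length encoded internally) is averaged
over 1-kb bins sliding by 200 bp, excluding repeat-masked positions from
numerator and denominator; bins containing any position above the
chromosome's maximum-depth threshold are deleted. The survey set that
threshold by eye; we use the 99.9th percentile of unmasked per-base depth
as a reproducible, configurable stand-in. GC correction is median-ratio by
integer GC percent stratum, with strata under 20 bins falling back to the
global median.

Corrected bin depths on each chromosome follow a five-class mixture over
CN ∈ {0..4}: a half-normal at zero for CN = 0,
$f_0(d) = \frac{2}{\sigma_0\sqrt{2\pi}} e^{-d^2/2\sigma_0^2}$, and normals
with mean $(k/2)\mu_2$ and variance $(k/2)\sigma_2^2$ for CN = k ≥ 1. Seven
parameters are free: $\mu_2, \sigma_2^2, \sigma_0^2$ and weights
$\pi_0, \pi_1, \pi_3, \pi_4$ (with $\pi_2$ implicit). The likelihood is
maximized directly with `stats::nlminb()` under box bounds
($\pi_0 \le 0.05$, $\pi_1 \le 0.2$, $\pi_3 \le 0.2$, $\pi_4 \le 0.05$,
$\sigma_0^2 \ge 0.01$) from starts $\mu_2 \leftarrow$ sample mean,
$\sigma_2^2 \leftarrow$ sample variance, $\sigma_0^2 = 1.5$,
$\pi = (0.01, 0.025, 0.001, 0.001)$ — interpreting "pseudo-maximum
likelihood" as one bounded optimizer call rather than EM. We supply the
analytic gradient and parameter scaling (depth-scale and weight-scale
parameters differ by four orders of magnitude); convergence tolerance is
1e-8 on the objective, and a fit with a weight pinned at a bound *and* a
singular Hessian is reported as failed, triggering the cross-chromosome
fallback (per-parameter arithmetic mean over the animal's successful
chromosomes, weights rescaled if their sum exceeds 1).

One printed artifact deliberately not matched: the source table lists the
CN = 0 component's mean as $\sqrt{2\pi}\sigma_0$, which is not the mean of
any standard half-normal ($\sigma_0\sqrt{2/\pi}$); we use the standard
density and treat the table entry as typographical.

Bins are assigned $CN = \arg\max_k \pi_k f_k(d)$ (the posterior mode; ties
break to CN = 2). A CNVR is **verified-consistent** if a test-animal bin in
the region is a CNV of the call's type; **verified-reference-effect** if
the test animal is diploid there but the *reference* animal shows the
opposite type (a reference deletion appears as a test duplication on the
array, and vice versa); **verified-discordant-type** if copy-number signal
exists but types disagree; otherwise **not-verified** (or **untestable**
with no usable bins, excluded from rates).

# Literature comparison and gene overlap

Overlap questions all use 0-based half-open arithmetic with "≥ 1 bp"
meaning intersection length ≥ 1; abutting intervals do not overlap. A
literature CNVR's "number of studies" is 1 plus the number of *other*
studies containing an interval overlapping it — the source never defines
its grouping, and this pairwise rule is the simplest consistent reading.
Gene overlap is against the union of CDS intervals (a CNVR spanning two
genes counts once). Duplications vs deletions are compared with a 2×2
chi-square without continuity correction (configurable). Enrichment uses
the same placement engine as the spatial null, 100 iterations by default;
the empirical p convention is add-one two-tailed,
$p = \min(1,\, 2\min(r_{hi}, r_{lo})/(n_{iter}+1))$ — the source's exact
two-tailed convention is unrecoverable (it reports p = 0.01 at 100
iterations, suggesting a one-sided convention), so both are provided via
`p_convention`.

# The synthetic world

`simulate_truth()` builds the stated world the tests run in: CNVR lengths
log-normal (median ≈ 9 kb, long right tail, floored at 1 kb), ≥ 1,500 bp
apart; a deletion fraction of 0.6 (the survey saw roughly 1.5 deletions
per duplication); Mendelian copy numbers from a biallelic locus with
Beta(1, 4) variant allele frequencies transmitted through sire–dam–progeny
trios, the reference animal a founder that can itself carry variants;
probes every 1,250 bp on autosomes so that carrier parents and progeny
share identical probe boundaries; Gaussian log2-ratio noise with sd 0.15
(no noise model is given by the source; 0.15 keeps a heterozygous deletion
at ~6.7 sd from zero); false calls Poisson per genome with the self-self
profile (3–6 probes, |l2r| 0.1–0.3); and homozygous-deletion ratios formed
with an effective-copy floor of 0.1 (array ratios stay finite).

Depth tracks are piecewise-constant per 1-kb block, each block drawn from
the CN-appropriate mixture component times a GC-bias factor, with
per-block GC around 0.42. The diploid block variance default is
$\sigma_2^2 = 6$ at $\mu_2 = 30$ (CV ≈ 8%), the realistic dispersion of
GC-corrected 1-kb bin means at ~10X coverage. This default matters: at
$\sigma_2^2 = 30$ (the configuration the *fit-recovery* test prescribes
for exercising the optimizer) adjacent CN classes overlap so much that no
classifier can reach the 95% per-bin accuracy the pipeline is expected to
achieve — the two statements are only jointly satisfiable with the less
dispersed generator, which is also the realistic one.

What a green synthetic run does **not** establish: segmentation itself is
not simulated (true calls inherit exact probe boundaries, so boundary
error is absent); depth noise is uncorrelated between blocks (real
coverage waves are long-range); GC bias is smooth and multiplicative;
repeat structure is random rather than clustered. Conclusions about those
failure modes need real data.

# Known limitations

* The stepwise search cannot distinguish near-collinear transforms of the
  same variable (see above); the selected *form* is reliable, term identity
  is not.
* The KS spatial test is conservative (see above); its p-values understate
  clustering evidence.
* No pseudo-autosomal region is modelled on X (none was defined).
* Breakpoint refinement, paired-end/split-read evidence and liftover
  between genome builds are out of scope; coordinates are assumed
  pre-mapped.
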