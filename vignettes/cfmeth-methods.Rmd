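---
title: "cfMethDx: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfMethDx: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models it
implements, the assumptions they rest on, the defaults and why they were
chosen, what the synthetic-data generator does and does not emulate, and
where genuinely open design choices were resolved.

## 1. The diagnostic model

### Fragment-origin inference

The core statistic is read-level. A cfDNA fragment covering CpG sites
$i = 1,\dots,k$ inside a marker region, with binary methylation calls
$s_i$, has log-likelihood under tissue group $g \in \{\text{mal},
\text{ben}\}$

$$\ell_g = \sum_{i=1}^{k} \big[ s_i \log p_{g,i} + (1-s_i)\log(1-p_{g,i})
\big],$$

where $p_{g,i}$ is the group-mean methylation (beta value) of site $i$
over the tissue reference methylomes, clamped into
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.01$. Assumptions:
CpGs are independent within a fragment given the tissue of origin
(no co-methylation haplotype model), and group means summarize the
reference distribution (no beta-binomial overdispersion). Both are the
minimal faithful model for a two-component mixture; the clamp guarantees
finite log-likelihood ratios, so a single discordant CpG can never veto
a fragment.

A fragment is called **malignant** when
$\mathrm{llr} = \ell_{\text{mal}} - \ell_{\text{ben}} \ge \log 2$,
**benign** when $\mathrm{llr} \le -\log 2$, and **ambiguous** otherwise
(ties, $\mathrm{llr}=0$, are ambiguous). The per-region **malignant
ratio** of a plasma sample is the fraction of its classified fragments
called malignant, with ambiguous fragments excluded, and is *missing* —
not zero — when fewer than `min_fragments = 5` fragments were
classified. Whether the original framework used hard per-fragment
classification or a mixture-style estimate is not determinable from its
description; both are implemented (`infer_config(estimator =
"posterior")` averages equal-prior posterior probabilities), hard
counting is the default because the reported quantity is a *ratio of
fragments*.

Only fragments with at least `min_cpgs_per_fragment = 3` calls inside
one region are informative: pattern-based inference needs a joint
pattern. Fragments whose CpGs span two regions go to the region holding
more of their CpGs (ties to the leftmost); containment of CpGs — not
interval overlap — is the assignment rule, because only CpGs carry
evidence.

### Size selection

Non-tumor cfDNA has a sharp mono-nucleosomal length mode at 167 bp;
ctDNA is shorter. Before origin inference, fragments are restricted to
the `short_window = c(90, 150)` bp band (after the global `< 500` bp
library rule). The window is a design default, not a reported value: it
captures the sub-mononucleosomal shoulder where the tumor:non-tumor
odds are severalfold enriched (about 2.9x under the default length
models) while keeping roughly a quarter of all fragments. Selection is
applied *before* region assignment (the alternative order is not
determinable from the source framework; a flag on `infer_config`
changes the window or disables it).

### DMR calling

Candidate regions are maximal runs of CpGs with inter-CpG gaps
$\le$ `max_gap_bp = 500` and at least `min_cpgs = 4` sites — the region,
not the CpG, is the unit of inference and of multiple-testing
correction. Per region, per-sample mean betas are compared between
groups with an exact Wilcoxon rank-sum test (a t-test is a flag);
rank-based is the robust choice at $n \approx 10$ per group.
Benjamini–Hochberg ranks are tie-broken by larger $|\Delta\beta|$ so
output is deterministic. A region is a DMR when $q \le 0.05$ *and*
$|\Delta\beta| \ge 0.2$; direction is the sign of
$\bar\beta_{\text{mal}} - \bar\beta_{\text{ben}}$. Only hypo-DMRs enter
the default marker panel: cfDNA coverage is systematically depleted in
the CpG-dense regions where hyper-DMRs live, so hypomethylated regions
are where plasma actually yields informative fragments.

### Scores, combination, cutoff

The 10 markers with the best single-marker AUC (ties by rank-sum p, then
id) feed a 500-tree probability random forest
(`mtry = floor(sqrt(p))`, minimum node size 5), scored by stratified
10-fold cross-validation so that every discovery sample is scored by a
forest that never saw it; a refit on all discovery data scores external
cohorts. No pre-installed random-forest package exists in this
environment, so the forest (bagged CART, Gini splits, per-node feature
subsampling, leaf-probability averaging) is implemented in the package
(`src/forest.cpp`); it is the stock recipe, deliberately untuned — the
diagnostic signal is in the features.

The combined model is ridge (L2) logistic regression on the
standardized triplet [cfMeth, mammography score, ultrasound score], the
penalty chosen by internal stratified 5-fold CV on a log-spaced grid.
Out-of-fold cfMeth scores — not in-sample refit scores — feed the
combined model, the leakage-safe resolution of an ambiguity in the
source description. BI-RADS subcategory is not added as a third imaging
feature: it is derived from the same two readings and would only add
collinearity.

The operating threshold is the largest cutoff whose discovery
false-negative rate is *strictly below* 2% ("less than 2%" read as
strict). With 77 positives this permits at most one false negative
(1/77 = 1.3%). When no threshold can satisfy the bound (e.g.
`max_fnr = 0`), the minimal score minus a machine tolerance is returned
with a warning.

Evaluation reports the trapezoid AUC with a stratified nonparametric
bootstrap percentile 95% CI (2000 replicates; the CI method of the
source is unstated and DeLong would be an equally defensible choice),
the confusion matrix at the threshold, and per-stage detection with
DCIS (stage 0) reported as its own stratum, since how it was grouped
originally is unknown. Stage association uses Kendall's tau-b on the
ordered stages.

## 2. The synthetic world

The generator's defaults *are* the stated study design: 9 malignant and
10 benign tissue methylomes; a 77/77 discovery cohort and a 24/25
validation cohort; 10-fold CV; 10 markers; the 167 bp mode; the < 500 bp
retention rule; the < 2% FNR bound. Everything else is a modelling
choice, fixed once:

**Genome.** Two chromosomes of 5 Mb (desk-scale runtime), 2 kb windows.
Background CpGs are Poisson at 0.004/bp. Two denser element classes
shape the density landscape: *islands* (40 x 2 kb at 10x background,
60% anchored at promoters, flanked by 600 bp CpG-free shores so each
island segments into its own CpG run) and *clusters* (16 x 200 kb at
0.03/bp) standing in for the large hypomethylated blocks of tumor
genomes. Hyper-DMRs are planted on island runs and hypo-DMRs on cluster
runs, which reproduces the observed density asymmetry (hyper-DMRs
CpG-denser than hypo-DMRs) and places markers where the pipeline can
see them. GC content is generated as an increasing function of CpG
density plus noise, reproducing the coupling of the two axes.

*Why 200 kb clusters?* The real study had ~11x genome-wide coverage of
a 3 Gb genome; the desk-scale default (20,000 fragments over 10 Mb) is
~0.33x. At real-world marker widths almost no simulated fragment would
carry >= 3 CpGs of a marker, and per-region ratios would be missing by
construction. Scaling marker-region width up by roughly the coverage
deficit restores the *informative fragments per marker per sample*
(~25–30) that the method actually operates on. This is a deliberate
compression of the world, not an estimate of real DMR sizes.

**Methylomes.** Per-site baselines are beta-jittered around 0.15
(islands) and 0.85 (everything else — the canonical somatic gene-body
level); per-sample, per-CpG betas are beta-distributed around group
means with concentration 30. Planted DMRs shift the malignant group
mean by ±delta on whole CpG runs; shifts leaving [0.02, 0.98] are
clamped with a warning. The *tissue simulator's* default delta is 0.3
(a typical DMR); the *default study* plants delta = 0.6 markers,
because a 10-marker panel stands in for the extreme tail of a
~50,000-region genome-wide screen, where top effect sizes are large.

**Fragments.** Lengths are drawn from a discretized asymmetric-Laplace
mixture: main peak at 167 bp (scales 20 bp left / 10 bp right — the
mild left skew of real cfDNA), a 10% di-nucleosomal satellite near
334 bp, and a 1.2x modal-bin excess modelling the phased
over-representation of the exact nucleosome + linker length. The excess
makes the 1-bp-bin mode a property of the distribution rather than of
sampling noise (a smooth peak leaves adjacent bins within Poisson noise
of the mode even at $n = 10^5$). Tumor fragments use the same family at
mode 145 bp with a 5% satellite. Fragment starts are drawn per window
with weight $\exp(-w z)$ ($z$ = window CpG-density z-score, $w = 0.5$)
times a promoter factor of 0.5 — a multiplicative factor rather than a
larger $w$, because amplifying $w$ would *boost* CpG-sparse promoters,
whose $z$ is negative, instead of depleting them. Per-CpG calls are
Bernoulli draws from the origin group's mean beta, flipped with
probability 0.01 (conversion/sequencing error).

**Cohorts.** Benign samples have tumor fraction exactly 0. Malignant
tumor fractions are gamma (shape 4) with stage-conditional means DCIS
0.005, I 0.01, II 0.02, III 0.04 — plausible early-disease ctDNA
burdens whose *ordering*, not values, is what tests rely on; the real
cohort's tumor fractions are unknown. Stage mix defaults to 5/40/33/22%
(stage I–III in the proportions of the reported per-stage counts, plus
a small DCIS stratum). Imaging scores are ordinal 1–5 from
label-shifted latent normals (shift 1.0 SD), giving standalone imaging
AUC ≈ 0.76 — deliberately imperfect, since the point of the combined
model is that imaging alone is not enough.

**What the generator does not emulate.** No sequence-level simulation
(no bisulfite reads, no alignment errors beyond the flat flip rate), no
CNVs/SNVs, no non-breast tissue contribution to plasma, no GC-dependent
amplification bias, no co-methylation haplotype structure, no
between-patient variation in the non-tumor background methylome. A
green end-to-end test therefore establishes that the *pipeline
machinery* recovers planted signal at realistic signal-to-noise — not
that the method would achieve any particular AUC on real plasma.

## 3. Numerical choices

* Coordinates are 0-based half-open throughout (BED convention); a CpG
  site occupies 2 bp.
* Size-profile mode ties break toward the smaller length; BH rank ties
  break by larger effect; marker-selection ties break by rank-sum p and
  then id — every output is deterministic given `(config, seed)`.
* `select_cutoff` maximality: with $P$ positives and bound $f$, the
  threshold is the $(k+1)$-th smallest positive score where $k$ is the
  largest integer with $k/P < f$; FNR at the returned threshold is
  below the bound by construction.
* The reference clamp $\varepsilon = 0.01$ caps any single CpG's llr
  contribution at $\pm\log(99)$.
* Degenerate inputs: empty fragment sets error in `size_profile`
  (an empty histogram has no mode) but propagate as missing ratios in
  inference; constant features are dropped (with a warning) before the
  ridge fit; a single surviving feature falls back to an unpenalized
  logistic fit (the ridge limit glmnet cannot represent with one
  column).

## 4. Known limitations

* The forest is a compact reimplementation, not a tuned library; exact
  numerical agreement with randomForest/ranger is neither expected nor
  needed (scores enter downstream only through ranks and a monotone
  combiner).
* The per-fragment likelihood ignores within-fragment co-methylation;
  on real WGBS data this overstates the information in dense fragments.
* The 90–150 bp window and all marker-region widths are tuned to the
  synthetic world's coverage; real-data use should revisit both.
* With ~0.33x simulated coverage, per-marker ratios rest on ~25
  fragments, so single-cohort AUCs fluctuate by a few points across
  seeds; calibration claims (null AUC ≈ 0.5) are therefore asserted on
  ensembles of null cohorts, not single draws.
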