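---
title: "Comparative scoring of proximity-biotinylation bait panels"
author: "proxComp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative scoring of proximity-biotinylation bait panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxComp)
```

## The problem

Proximity biotinylation (BioID) panels relocate a family of baits — here,
nucleotide-locked small GTPases fused to a promiscuous biotin ligase and
anchored on the mitochondrial outer membrane — and ask which proteins become
biotinylated with each bait. Because every bait sits in the same location,
every pulldown shares a large common background: abundant cytosolic
proteins, mitochondrial residents, endogenously biotinylated carboxylases,
and the bait chimera itself. A specific interactor (an effector of the
GTP-locked form, or a GEF-like partner of the GDP-locked form) is
recognizable only *comparatively*: it is reproducible across the replicates
of its bait and rare or absent across the rest of the panel.

`proxComp` implements the two complementary scoring branches used for such
panels, and integrates them:

1. a **spectral-count branch** (CompPASS family: Z, D and WD scores), and
2. an **intensity branch** (label-free enrichment of each bait against a
   pooled GDP-state background, with downshifted-Gaussian imputation,
   Student's t tests and a permutation FDR),

plus a **synthetic panel generator** with a planted ground truth so that
every stage can be calibrated and benchmarked without raw mass-spectrometry
data.

## Spectral-count scores

For prey $i$ and bait $j$ in a panel of $K$ baits, let $\bar X_{ij}$ be the
mean total spectral count over the bait's $n_j$ replicates and
$p_{ij}$ the number of replicates with a non-zero count. Across the whole
panel (zero-count baits included) define, per prey, the bait frequency
$f_i = \#\{j : p_{ij} > 0\}$, the mean $\mu_i$ and the ($n{-}1$) standard
deviation $\sigma_i$ of the bait-level means, and the variability weight
$\omega_i = \max(1, \sigma_i / \mu_i)$. Then

$$Z_{ij} = \frac{\bar X_{ij} - \mu_i}{\sigma_i}, \qquad
  D_{ij} = \sqrt{\bar X_{ij}\,(K/f_i)^{\,p_{ij}}}, \qquad
  WD_{ij} = \sqrt{\bar X_{ij}\,\big((K/f_i)\,\omega_i\big)^{\,p_{ij}}}.$$

The D score rewards preys found reproducibly ($p$ in the exponent) with few
baits ($K/f$ large). The WD variant additionally up-weights preys whose
counts with a *subset* of baits stand above the panel-wide background level
— the signature of an effector shared by a few related GTPases, which the
plain D score would punish through $f$.

Numerical choices, fixed once:

* $\bar X$ is the **mean** of replicate counts, not the sum, so scores are
  invariant to the replicate number; summing is available via
  `aggregate = "sum"`.
* The exact weight in the WD variant is a design decision here (the score
  family defines it only loosely): $\omega = \max(1, \sigma/\mu)$ over the
  bait-level means, floored at 1 so that low-variability preys are never
  *down*-weighted and $WD \ge D$ always holds. The floor also gives the
  clean identity $WD = D$ wherever $\omega = 1$.
* $\sigma = 0 \Rightarrow Z = 0$: a prey found at identical levels with
  every bait is uninformative, not infinitely significant.
* Detection for $p$ and $f$ is count $> 0$ — any spectral evidence counts.
* Optional percentile normalization of WD (`normalizeWD()`) divides by the
  panel-wide WD quantile computed with linear interpolation between order
  statistics (R's default quantile type 7). It is **off** by default;
  bubble sizing uses the raw $\sqrt{WD}$.

## Intensity branch

The label-free branch mirrors the standard volcano-plot workflow on a
proteinGroups-style table:

1. **Cleanup** — reverse-decoy and identified-only-by-site rows are removed;
   duplicate gene rows are collapsed to the highest-total row; potential
   contaminants are flagged but kept (the comparative design handles shared
   background better than blanket removal).
2. **Log transform** — intensities to log2; zero (not detected) becomes the
   missing marker.
3. **Valid-value filter** — keep preys with at least `minValid = 2` valid
   values in the replicate group of at least one bait, applied once,
   globally, before all contrasts.
4. **Imputation** — missingness in label-free data concentrates at low
   abundance (missing not at random), so each missing entry in sample
   column $s$ is drawn from
   $\mathcal N(m_s - 1.8\,\mathrm{sd}_s,\ (0.3\,\mathrm{sd}_s)^2)$,
   where $m_s$, $\mathrm{sd}_s$ are the observed mean and SD of that column
   (units: log2 intensity). Width 0.3 and downshift 1.8, per column, are
   the conventional defaults of this imputation family. Observed values are
   never touched.
5. **Contrasts** — each GTP-locked bait against the pooled replicates of
   *all* GDP-locked baits (effectors do not bind the GDP form, so the
   pooled GDP panel is a valid negative set — including the same GTPase's
   own GDP form); each GDP-locked bait against all *other* GDP-locked baits
   (exchange factors act on one or two GTPases, so the other GDP baits are
   the right background for GEF hunting). Ligase-only controls get no
   contrast.
6. **Test** — equal-variance two-sample Student's t on log2 intensities,
   $df = n_1 + n_2 - 2$; `log2fc` is the difference in group means. An
   optional fudge factor `s0` (default 0) is added to the standard error.
   Degenerate guard: zero pooled SE with equal means gives $t=0, p=1$; with
   unequal means, the smallest positive double as p.
7. **FDR** — by default a permutation scheme with `nPerm = 250`
   relabelings of the contrast's samples:
   $$\mathrm{FDR}(i) = \frac{\frac1B\sum_b \#\{j: |t^{(b)}_j| \ge |t_i|\}}
                            {\#\{j: |t_j| \ge |t_i|\}}$$
   clipped to $[0,1]$ and made monotone non-increasing in $|t|$ by step-up
   smoothing (each prey takes the minimum raw value over itself and all
   less significant preys, as in Benjamini–Hochberg). When the number of
   distinct relabelings is at most `nPerm`, all of them (identity included)
   are enumerated exactly once, so the result is an exact brute-force
   computation; otherwise relabelings are sampled, excluding the identity.
   Benjamini–Hochberg on the analytic p-values is available via
   `fdrMethod = "BH"`.

## Integration

`assembleBubbleVolcano()` joins the two branches into one record per
post-filter prey per contrast: $x$ = log2 fold change, $y$ = $-\log_{10} p$,
point size proportional to $\sqrt{WD}$ (the square root keeps the full
range of sizes visible on one plot), scaled so the panel-wide maximum gets
`sizeMax`. The bait's own gene is scored normally but *excluded at export*
— its self-signal would dwarf every real hit — and endogenously
biotinylated carboxylases (ACACA, PC, PCCA, PCCB, MCCC1, MCCC2 by default)
are flagged, never dropped. `rankHits()` orders by descending WD (or
ascending p) with deterministic lexicographic tie-breaking on the prey
identifier, and can attach the test bait's per-replicate counts for
replicate-dot reporting.

## The synthetic panel generator

`simConfig()`/`generatePanel()` draw a panel with the structure the scoring
assumes. Per prey $i$, a base abundance $\log_2 A_i \sim
\mathcal N(\texttt{bgLoc}, \texttt{bgScale})$ shared by all baits emulates
the common-location background; mitochondrial residents sit
`mitoBoost` log2 units higher; biotin carriers and the bait protein carry
large multipliers. Counts are negative binomial,
$\mathrm{NB}(\mu = \texttt{captureRate}\cdot A_i \cdot F_{ij},\
\mathrm{size} = \texttt{dispersion})$ — overdispersion is the norm in
spectral counting, and large `dispersion` recovers the Poisson limit.
Intensities are $\log_2 I = \texttt{intensityOffset} + \log_2(A_i F_{ij}) +
\mathcal N(0, \texttt{intensityNoiseSd})$, observed with probability
$\mathrm{logit}^{-1}((\log_2 I - \texttt{detectMidpoint}) /
\texttt{detectSlope})$ — dropout is therefore missing not at random, the
regime the imputation targets.

$F_{ij}$ is the enrichment factor: `foldEffector` for an effector in its
GTP bait, `foldGef` for a GEF-like prey in its GDP bait, and so on. A
deliberate design choice is **`bystanderCapture`** (default 0.01): a planted
specific interactor is captured in its *non*-target samples at only 1 % of
normal efficiency. This reflects how such panels actually behave — a
soluble effector is biotinylated efficiently only while bound to its bait,
and shows essentially zero counts with non-cognate baits — and it is what
makes the bait-frequency term $f$ informative. The suppression applies only
to preys with fold > 1, so a panel generated with all folds set to 1 is
exactly exchangeable background, which is what the null-calibration tests
require.

Default scales (chosen once, as a realistic desk-scale panel): 3 GTPase
pairs × 3 replicates, 1,000 background preys, `bgLoc` 7 / `bgScale` 1.5
(log2 abundance), `captureRate` 0.05 (≈ 6 spectral counts for a median
background protein), `dispersion` 4, intensity offset 18 with noise SD 0.4
log2 units, detection midpoint 22 / slope 1 (≈ 95 % detection for a median
protein, steeply less below). The generator emulates the *statistical*
structure of a panel — shared background, state-specific enrichment,
overdispersion, abundance-dependent dropout — and deliberately not
peptide-level quantification, between-run normalization drift, or batch
effects; passing the recovery benchmarks therefore validates the scoring
machinery, not the upstream quantification of real data.

## Worked example

```{r example, eval = FALSE}
cfg <- simConfig(nPairs = 3, nBackground = 1000, nEffectors = 10,
                 nGefs = 10, nShared = 0, nNucIndep = 0, seed = 1)
panel <- generatePanel(cfg)
compass <- computeCompass(panel$counts)
enrich  <- runEnrichment(panel$intensity, nPerm = 250, seed = 1)
bubble  <- assembleBubbleVolcano(enrich, compass, panel$design)
ranked  <- rankHits(bubble, key = "WD", counts = panel$counts)
evaluateRecovery(ranked, panel$truth, k = 15)
```

The same pipeline runs from files via `simulatePanelFiles()` /
`runScorePipeline()` / `reportFromPrefix()`, or from a shell through the
thin wrapper in `inst/scripts/proxcomp.R`.

## Reproducibility and problem sizes

All randomness (simulation, imputation, permutations) is seeded; a single
pipeline seed deterministically derives per-stage sub-seeds so stages can
be re-run in isolation, and a fixed seed makes the full file-to-file
pipeline byte-reproducible. The test suite exercises the scoring oracle on
200 random panels (K ≤ 8, ≤ 50 preys), imputation calibration on 50,000
imputed values, null calibration on a 2,000-prey panel, and recovery on a
1,000-background-prey panel with 10 planted effectors per GTP bait and 10
GEF-like preys per GDP bait at 8-fold enrichment — sizes chosen so the
whole suite runs in well under a minute of compute per block.

## Known limitations

* The exact weight of the WD variant is pinned here as
  $\max(1, \sigma/\mu)$; published WD implementations differ in detail, so
  absolute WD values are not comparable across software — rankings are the
  robust output.
* The mean-based permutation FDR is conservative near its resolution limit
  on small panels: with 3 bait pairs a GDP-vs-other-GDP contrast has only
  84 distinct relabelings, and relabelings that recapture another bait's
  planted triple contaminate the null, flooring attainable FDR values near
  0.05. The effect vanishes as the panel grows (the study-scale 17-pair
  design has $\binom{51}{3}$ relabelings per contrast). The
  Benjamini–Hochberg alternative does not share this floor.
* No between-run normalization is applied; label-free intensities are
  assumed normalized upstream.
* No variance moderation (empirical Bayes) is used — the branch matches
  the plain two-sample Student's t of the standard volcano workflow.
* Known-interactor annotation is user-supplied; the package does not curate
  effector/GAP/GEF categories from databases.
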