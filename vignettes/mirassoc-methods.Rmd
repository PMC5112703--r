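---
title: "Mining miR-mRNA repression from paired abundance panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining miR-mRNA repression from paired abundance panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirassoc)
```

## The problem

MicroRNAs (miRs) repress mRNA targets post-transcriptionally. When a miR
destabilises its target transcript, the signature across a panel of related
samples — here, melanoma cell lines spanning the proliferative/epithelial-like
to invasive/mesenchymal-like spectrum — is a strong *negative* association
between miR abundance and target mRNA abundance. Sequence-based prediction
databases propose very large candidate sets; abundance data alone propose
many spurious associations. `mirassoc` screens every miR x mRNA-probe pair
with two complementary association statistics and then intersects the strong
negative tail with high-confidence database predictions, yielding a compact
table of putative repressive relationships annotated with validation status
and a phenotype-separation score.

## The screening model

For each retained pair $(x, y)$ of log2 abundance vectors across $N$ samples
the pipeline computes:

* **Pearson's correlation** $r_P$, which captures linear association and
  carries the sign (repression should be negative);
* **mutual information** $I(X; Y)$, which captures any deviation from
  independence, including monotone but saturating (e.g. sigmoidal)
  repression that depresses $|r_P|$.

MI is estimated with the Kraskov–Stoegbauer–Grassberger *algorithm 2*
k-nearest-neighbour estimator. After a seeded uniform dither of amplitude
$10^{-8}$ breaks ties (expression matrices contain many exact zeros), the
$k$-th nearest neighbour of each point is found under the max-norm in the
joint space; $\epsilon_x(i)/2$ and $\epsilon_y(i)/2$ are the largest
marginal distances over those $k$ neighbours, $n_x(i)$ and $n_y(i)$ count
points inside the closed marginal balls (self excluded), and

$$\hat I = \psi(k) - \tfrac{1}{k}
  - \big\langle \psi(n_x) + \psi(n_y) \big\rangle + \psi(N)$$

in nats. The digamma terms debias the estimate; near independence the
estimate can be slightly negative, and no further correction is applied.
Defaults: $k = 4$ (the common toolkit default; the neighbour count is
exposed as a parameter), output in nats. The estimator is implemented in
C++ for the full pair grid and is checked in the test suite against (i) a
naive brute-force reference (bitwise agreement), (ii) the closed form
$-\tfrac12\log(1-\rho^2)$ for bivariate Gaussians, and (iii) independent
samples.

Selection takes the *intersection* of the two tails: MI strictly above its
top-10% quantile and $r_P$ strictly below its most-negative-2.5% quantile
(linear-interpolated quantiles; both percentages are parameters, and an
"or" mode exists but is off by default). Cutoffs are data-dependent, so the
realised values are persisted in the run manifest — they are the
reproducibility record for a given panel.

## Preprocessing

Features with low abundance or a compressed dynamic range mostly contribute
noise. Two rules are applied, with all thresholds computed from the pooled
input matrix:

1. **Abundance** — the pooled 10th percentile of all values in a matrix is
   the detection threshold; a feature must have at least
   $\lfloor 0.25\,n \rfloor$ samples strictly above it (14 of 57 at the
   default panel size). The floor convention matches the natural reading of
   a 14-of-57 cutoff; a strict-25% reading would demand 15, and the
   fraction is a parameter for users who prefer it.
2. **Range** — a miR's range (max − min) must exceed the pooled 90th
   percentile of miR abundance *values*; an mRNA probe's range must exceed
   10% of the global mRNA value range. The miR rule is deliberately the
   literal "percentile of the abundance data" reading; an alternative mode
   (`mir_range_mode = "ranges"`, the 90th percentile of per-feature ranges)
   is provided because the abundance-value reading is aggressive — on a
   panel with many never-detected miRs it retains only the strongly
   dynamic minority, which is also what gives the association screen its
   signal.

Filtering is idempotent by construction: thresholds travel with the report
and are not recomputed on the filtered output. Quantile normalisation
(per-rank cross-sample means) and log2 transformation are available for
inputs arriving on a raw scale; the synthetic generator emits log2 values
directly, so the pipeline default applies neither.

## Database integration

Sequence-based predictions are percentile-filtered per source on the
*global* score distribution: the most negative 15% of context+-style
scores and the largest 30% of miTG-style scores (a single printed cutoff
per source is only consistent with a global, not per-miR, distribution;
the realised cutoff is reported). Duplicate (miR key, gene) records keep
the best score for their source. Family-keyed records fan out to every
mature miR of the family through the identifier map; probes fan out to
every mapped gene symbol, and unmapped probes are flagged, never silently
dropped. Validated interactions count as strong evidence only for the
exact methods *Luciferase reporter assay*, *qRT-PCR* or *Western blot*
(case-insensitive, trimmed, exact match — substring matching would admit
compound method strings of mixed strength).

A putative relationship is a selected association whose (miR-or-family,
gene) pair survives at least one filtered prediction source; the validated
flag is an annotation, not a requirement.

## Enrichment

The per-miR enrichment of "active" associations is a reconstruction — the
quantity is described in the field as a relative enrichment without a
printed formula. We define, per source and per miR, the observed fraction
of predicted-in-universe pairs that are active, divide by the pooled
background fraction across all miRs, and attach a one-sided hypergeometric
tail $P(X \ge n_{active})$ as a significance companion. Both components
are reported so either can be ranked on. Two invariants pin the
definition down: a single-miR universe has fold exactly 1, and the pooled
universe treated as one miR has fold 1.

GO categories are selected by case-insensitive name substrings (defaults:
`epith`, `mesench`, `pigment`, `melan`) with 5–500 gene members inclusive;
the target-list fraction uses the *union* of the selected categories'
members (one loading per bundle, EMP and Pigmentation), at gene level
after probes collapse to symbols.

## Phenotype separation

For a pair with high/low invasiveness labels on a subset of samples, the
group centroids are arithmetic means of the labelled samples' log2
abundances per axis. "Centroid/geometric mean" is ambiguous in the field's
usage; the arithmetic mean of log2 values *is* the log2 geometric mean on
the linear scale, so the two readings coincide and we use it. With

$$d_{Sep,max} = \sqrt{(\max[mRNA]-\min[mRNA])^2 + (\max[miR]-\min[miR])^2}$$

taken over *all* samples with data (the equations reference the plain
ranges without group restriction; a labelled-only mode is available), the
score is the centroid distance divided by $d_{Sep,max}$, which lies in
$[0,1]$, is group-symmetric and ignores unlabelled samples inside the
ranges. Percentile ranks (mid-ranked ties, $100(r-0.5)/n$) are computed
across every association that passed preprocessing, not only the putative
subset.

## The synthetic study generator

The generator produces every pipeline input with the statistical structure
the analysis assumes, at the scale of the motivating panel: 57 samples,
2592 miRs of which a ~35% fraction have no reads in any sample, tens of
thousands of probes, 24 phenotype-labelled samples, and a reduced-scale
barcode-keyed cohort (10 samples from 9 patients, one patient contributing
two samples).

Design choices, fixed once:

* Log2 abundances are generated directly: stable features draw a baseline
  mean from Normal(6, 2) across features with modest within-feature spread,
  mimicking sequencing/microarray dynamic range and giving realistic pooled
  10th/90th-percentile behaviour.
* A fraction of miRs (default 15%) are bimodal "on/off" across samples —
  lineage-restricted expression — with high-state means near 9 log2 units.
  Only such miRs carry enough dynamic range to support detectable
  repression, so planted pairs always use them; they are also what the
  literal miR range filter retains.
* Planted repression: linear pairs obey
  $y = a + s\,x + \varepsilon$, $s \sim U(-2, -0.5)$,
  $\varepsilon \sim N(0, 0.5^2)$; a 30% fraction use the monotone
  decreasing logistic $a - b/(1+e^{-s(x-x_0)})$ with $b > 0$, detectable
  by MI while depressing $|r_P|$.
* Phenotype-linked pairs shift the miR by $\pm$ half the group effect
  between labelled groups *before* the target is generated, so the shift
  propagates mechanistically to the mRNA.
* Prediction tables: planted pairs enter each source with probability
  `db_coverage`, scored inside the source's high-confidence tail (as
  genuinely repressive pairs score in real databases); decoys draw from
  the full score range. Validated records sample methods including
  *Microarray*, so the strong-evidence filter is exercised.
* One seeded RNG stream per generator call (fixed offsets from the
  config seed), giving byte-identical outputs per config + seed without
  global state.

What the generator does **not** emulate: read-level sequencing error,
copy-number structure, correlated co-regulation among null features,
batch effects, and the heavy-tailed joint distribution of real panels.
Passing tests therefore demonstrate that the method recovers the planted
structure under idealised independence assumptions — not that real-data
headline numbers are reproduced. Reproducing those requires the deposited
panel data, which the pipeline accepts via explicit input paths.

## Numerical choices and degenerate inputs

* Quantiles are linear-interpolated (R type 7) throughout; thresholds are
  applied with strict inequality on the favourable side, and a 100% tail
  keeps everything.
* Tie-breaking dither: amplitude $10^{-8}$, drawn once per matrix from the
  run seed; MI is symmetric in its arguments by construction.
* Constant features are excluded from association (correlation undefined)
  with a warning; degenerate (all-equal) association distributions yield
  an empty selection with a warning; an all-dropped filter, an empty
  barcode intersection, a zero $d_{Sep,max}$ and an empty labelled group
  are errors.
* Test and calibration problem sizes were chosen as the package's own
  working points: KSG calibration at $N = 2000$ with 20 seeds per
  correlation; planted-pair recovery on 100 miR x 1000 probe panels at 57
  samples over 10 seeds; hypergeometric enumeration over all urns with
  $N \le 25$.

## Known limitations

* The per-miR enrichment formula is a documented reconstruction; reported
  folds are validated by their internal invariants only.
* The miR range filter's literal reading retains few, strongly dynamic
  miRs; panels with compressed dynamic range should consider
  `mir_range_mode = "ranges"`.
* MI estimates at $N = 57$ are noisy (that is intrinsic to the panel
  size); the percentile-based selection is a ranking, not a significance
  statement, and no multiple-testing control is attempted by design.
* Cohort matching pairs samples by exact full-length barcode only; no
  fuzzy patient-level collapsing is attempted.
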