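# mirassoc

Integrative mining of microRNA–mRNA repression from paired abundance
panels.

## What it is for

Across a panel of related samples — the motivating case is a collection of
melanoma cell lines spanning proliferative/epithelial-like to
invasive/mesenchymal-like phenotypes — a miR that destabilises a target
mRNA leaves a strong *negative* association between the two transcripts'
log2 abundances. `mirassoc` is for computational biologists who want to
turn a paired miR/mRNA expression panel plus target-prediction and
validation tables into a short, annotated list of putative repressive
relationships, with every data-driven threshold recorded for
reproducibility.

The pipeline:

1. **Preprocess** — drop features with low abundance (fewer than
   ⌊0.25·n⌋ samples strictly above the pooled 10th-percentile value) or a
   compressed dynamic range (miR range ≤ pooled 90th-percentile value;
   mRNA range ≤ 10% of the global range).
2. **Associate** — for every retained miR × probe pair compute Pearson's
   r and the Kraskov–Stoegbauer–Grassberger algorithm-2 k-NN mutual
   information (k = 4, nats, in C++):
   `Î = ψ(k) − 1/k − ⟨ψ(n_x) + ψ(n_y)⟩ + ψ(N)`.
3. **Select** — keep the intersection of the tails: MI above its top-10%
   quantile *and* r below its most-negative-2.5% quantile.
4. **Integrate** — keep selected pairs supported by the most negative 15%
   of context+-style predictions and/or the largest 30% of miTG-style
   predictions; flag pairs validated by luciferase reporter assay,
   qRT-PCR or Western blot.
5. **Enrich** — per-miR fold enrichment of active associations with a
   hypergeometric tail p, and GO substring enrichment (epith/mesench,
   pigment/melan; 5–500 members) of the combined target list.
6. **Separate** — score each pair by `d_Sep,norm`: the distance between
   the high- and low-invasiveness group centroids in the (miR, mRNA)
   plane, normalised by the maximal span
   `d_Sep,max = √(range[mRNA]² + range[miR]²)`, with percentile ranks
   across all tested associations.

A seeded synthetic-data generator (`simulate_study()`) produces all
inputs — panels with planted linear and sigmoidal repression, prediction
tables with decoys, GO annotations, phenotype labels, a barcode-keyed
cohort — so the whole pipeline is testable without any downloads.

## Worked example

```r
library(mirassoc)
out <- file.path(tempdir(), "demo_run")
cfg <- pipeline_config(list(seed = 1, out_dir = out,
  simulate = list(n_mirs = 100, n_mrnas = 1000, n_true_pairs = 30,
                  db_coverage = 1, n_decoys = 5000)))
man <- run_pipeline(cfg)
summary(man)
```

```
filter_features [miR]: retained 25/100 (abundance thr 0, >= 14 samples above; range thr 9.198)
filter_features [mRNA-probe]: retained 766/1000 (abundance thr 4.694, >= 14 samples above; range thr 2.639)
selection: mi > 0.09934 and r < -0.2674 -> 126/19150 associations
targetscan: realised score cutoff < -1.036 (kept 728/4850)
diana: realised score cutoff > 0.7041 (kept 1509/5030)
<mirassoc_run> stages: simulate > preprocess > associate > select > integrate > enrich > dsep
  retained 25 miRs, 766 probes
  19150 associations
  selected 126 (mi > 0.09934, r < -0.2674)
  putative relationships: 27
  prediction cutoffs: context+ < -1.036, miTG > 0.7041; validated-strong 12
  d_sep scored pairs: 19150
```

Reading this: of the 100 simulated miRs only the 25 with a genuinely
dynamic expression pattern survive the range filter (the planted
repressors are all in there); 19,150 pairs are scored; 126 fall in both
selection tails, and 27 of them are backed by a filtered prediction
source. The strongest rows of `putative.tsv`:

```
         mir_id gene_symbol  pearson_r  mi_nats targetscan_support diana_support mirtarbase_validated d_sep_norm d_sep_rank_pct
   sim-miR-0058  SGENE00011 -0.9989877 1.726220               TRUE          TRUE                FALSE 0.27701186       93.69452
   sim-miR-0077  SGENE00506 -0.9978670 1.489026               TRUE          TRUE                FALSE 0.14631955       76.94778
   sim-miR-0003  SGENE00344 -0.9975570 1.178041               TRUE          TRUE                FALSE 0.07720949       44.92167
```

Each row is a selected association (its r and MI exceed the realised
cutoffs) supported by both prediction sources; `d_sep_rank_pct` places the
pair's phenotype separation among all 19,150 tested associations — the
top row separates the high/low-invasiveness groups better than ~94% of
them. Every stage table (`associations.tsv`, `selected.tsv`,
`putative.tsv`, `enrichment_mir.tsv`, `dsep.tsv`) and `manifest.json`
with all realised thresholds are under `out`.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/mirassoc run-all --config config.yaml
Rscript inst/cli/mirassoc simulate --seed 1 --out run1
```

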