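# dnbpipe

Tipping-stage detection and early-warning biomarker selection for staged
proteomics.

## The problem

Progressive diseases sampled at ordered histological stages — here the
esophageal squamous series ESO (esophagitis) < MID (mild dysplasia) <
MOD (moderate dysplasia) < SED (severe dysplasia) < ESCC (carcinoma),
profiled in lesion (L) and adjacent non-lesion (N) tissue — often do not
progress smoothly: somewhere along the series the molecular system crosses
a tipping point into a qualitatively different, largely irreversible
state. Locating that stage matters clinically (it is the intervention
window) and analytically (it defines the "pre" vs "post" phases that
downstream differential expression and classifier construction compare).

`dnbpipe` implements the dynamic network biomarker (DNB) approach to this
problem for protein expression matrices, together with the surrounding
pipeline: preprocessing, normality-gated differential expression with
fold-change bounds, fuzzy c-means trend clustering, EMT signature scoring,
SVM-RFE biomarker-panel selection with cross-validated AUC, and
ligand-receptor crosstalk ranking between compartments. Because staged
biopsy cohorts are rarely deposited, the package also ships a synthetic
staged-dataset generator with planted ground truth, used by the entire
validation suite.

## The core statistic

At each stage *s*, a candidate protein module *M* (found by
average-linkage clustering on 1 − |PCC|) is scored by the composite index

    CI(M, s) = SD_in · PCC_in / max(PCC_out, ε)

where SD_in is the mean within-stage standard deviation of the members,
PCC_in the mean absolute pairwise-complete Pearson correlation among
members, and PCC_out the mean absolute correlation between members and
all other proteins. A module whose fluctuation and internal coupling
spike while its external coupling drops — the DNB early-warning signature
— maximises CI; the stage with the maximal best CI is called the tipping
stage, and stages up to and including it form the pre phase. Significance
is assessed by permuting sample-to-stage assignments.

## Worked example

```r
library(dnbpipe)

ds     <- generate_staged_dataset(synthetic_config(seed = 1))
design <- build_stage_design(ds$annotations)
mat    <- filter_by_completeness(median_normalize(ds$matrix), design,
                                 min_frac = 0.5)
mat
#> expr_matrix: 2000 proteins x 112 samples (log2 scale), 20.0% missing

dnb <- detect_tipping_stage(mat, design, compartment = "L")
dnb
#> dnb_result (L): tipping stage MID, 22 members
#>   ESO   MID   MOD   SED  ESCC
#> 1.799 5.237 1.834 2.393 1.880
```

The CI curve peaks at MID — the stage where the generator planted a
15-protein module with correlation 0.8 and a 3-fold variance spike — so
MID is called the tipping stage; the reported module overlaps the planted
one at Jaccard 0.61. The call then drives the phase split and the
downstream comparisons:

```r
phases <- split_phases(default_stage_order(), dnb$tipping_stage)
de <- de_table(mat, design_samples(design, "L", phases$post),
               design_samples(design, "L", phases$pre))
head(de[, c("protein_id", "fc", "log2fc", "p_value", "call")], 3)
#>   protein_id       fc   log2fc      p_value call
#> 1      P0022 2.206938 1.142046 1.672451e-11   up
#> 2      P0017 2.068965 1.048909 5.379985e-09   up
#> 3      P0016 2.377955 1.249721 4.890025e-08   up

sc  <- signature_score(mat, ds$truth$emt_sets$mesenchymal,
                       ds$truth$emt_sets$epithelial)
cmp <- compare_phase_scores(sc, phases, design, "L")
#> EMT score post - pre = 0.952 (p = 1.5e-07, student_t)
```

The top up-calls are the planted panel members (a +1 log2 shift in the
post phase; fold changes near 2), and the EMT score — mean mesenchymal
minus mean epithelial expression per sample — rises by ~0.95 log2 units
across the phase boundary, close to the planted drift of 0.15 per stage
rank accumulated over the series.

A single call runs everything (preprocess → DNB → phases → DE → clusters
→ EMT → panel → crosstalk) and writes TSV outputs plus a deterministic
`report.json`:

```r
report <- run_pipeline(pipeline_config(seed = 1, output_dir = "run1"))
```

A thin command-line runner over the same function lives at
`inst/scripts/run_pipeline.R` (YAML configuration, see
`?pipeline_config`).

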