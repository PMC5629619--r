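# linkdrp

Drug sensitivity prediction for cancer, recast as link prediction.

## The problem

Given a panel of cancer cell lines with expression profiles
(X ∈ ℝ^{p×n}) and continuous drug responses (IC50 values y ∈ ℝ^p), predict
the response of patient tumors (T ∈ ℝ^{q×n}, same genes) to the same drug,
and rank them well against their binary clinical outcome
(sensitive/resistant). The audience is computational pharmacogenomics:
anyone transferring cell-line drug screens to clinical cohorts.

`linkdrp` implements a link-prediction approach to this transfer task:

1. **Paired features.** Each sample is re-represented as the concatenation
   of its own profile `g_i` with a synthetic partner
   `g_b = g_i + (g*_j − g_i)·λ`, interpolated toward its nearest neighbor
   `g*_j` (defaults λ = 0.3, k′ = 1), giving 2n feature columns.
2. **Link filtering (relaxed query-by-committee).** Training cell lines are
   weighted by `w_i = min_j dist(g_i, g′_j)`, the minimum Euclidean distance
   to the test tumors; the median weight splits them into a near half X and
   a far half Z; cross-prediction with a ridge seed learner decides which
   half seeds the labeled pool S; then k″ = 5 rounds of committee
   disagreement (three equally weighted SVRs: linear, degree-5 polynomial,
   sigmoid) each move the most-disputed row from the unlabeled pool into S.
3. **Optional leverage-score gene selection.** Columns of the filtered set
   are ranked by CUR normalized statistical leverage scores
   `π_j = (1/l) Σ_ξ (v_j^ξ)²` and the top k are kept at identical positions
   in train and test.
4. **Final fit.** Ridge regression or SVR is fitted on the filtered
   (possibly column-reduced) set and scores every tumor.
5. **Evaluation.** AUC per run, MAUC over a decreasing training-size
   schedule, two-tailed Wilcoxon signed-rank tests between algorithms, and
   group t-tests between clinical groups.

The three pipelines are exported as `runBaseline()` (fit directly on raw
matrices), `runA1()` (paired features + link filtering), and `runA2()`
(A1 + leverage selection).

## Worked example

```r
library(linkdrp)

# synthetic cohort: 60 cell lines, 30 tumors, 20 genes, 6 informative
ds <- syntheticDataset(p = 60, q = 30, n = 20, nInformative = 6,
                       effectSize = 1.5, noiseSd = 0.5, seed = 11)

pred <- runA1(ds$D, ds$y, ds$T, finalLearner = learnerSpec("rr"))
round(head(pred), 3)
#>  TM001  TM002  TM003  TM004  TM005  TM006
#> -0.365 -1.744 -0.856 -0.230 -4.197  5.567
attr(pred, "selectedSize")   # 35 = p/2 + k'' filtered training rows
attr(pred, "featureCount")   # 40 = 2n paired feature columns
aucScore(pred, ds$labels)
#> 0.902
```

Predictions are on the IC50 scale: higher means more resistant, and the AUC
measures how well they rank resistant (label 1) tumors above sensitive
ones — here 0.902 on a planted linear signal. The full harness:

```r
rep <- runBenchmark(ds$D, ds$y, ds$T, ds$labels,
                    algorithms = c("B", "A1"),
                    learners = list(learnerSpec("rr"), learnerSpec("svr-linear")),
                    sizes = c(60, 57, 54), seed = 2)
rep
#> EvalReport: 3 runs x 4 algorithm combinations
#>   MAUC:
#>     B+rr             0.976
#>     B+svr-linear     0.948
#>     A1+svr-linear    0.907
#>     A1+rr            0.904
```

`perRunAUC(rep)` returns the run-by-run AUC table, `pairwiseWilcoxon(rep)`
the cross-algorithm signed-rank p-values, and `writeEvalReport(rep, path)`
dumps everything as JSON. (On easy i.i.d. synthetic signal the baseline is
hard to beat; the filtering step targets cohort mismatch that this toy
generator deliberately does not contain — see the methods vignette.)

Delimited-text I/O (`readExpressionMatrix()`, `readResponseVector()`,
`readClinicalLabels()`, `writePredictions()`) and a thin command-line
wrapper (`inst/scripts/linkdrp.R` with `run`, `synth`, and `evaluate`
subcommands) are included for shell use.

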