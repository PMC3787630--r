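# gcxgcalign

Peak matching alignment for comprehensive two-dimensional gas
chromatography mass spectrometry (GCxGC-MS) peak lists, for
metabolomics workflows that must recognize the same compound across
runs before any differential analysis is possible.

Each detected peak carries two retention times $(r_1, r_2)$ and a
fragment mass spectrum $X = (x_1,\dots,x_g)$ on a nominal-mass m/z
grid. The package provides:

* **Five mass spectral similarity measures** — cosine (dot product),
  Pearson, Spearman, partial correlation and part (semipartial)
  correlation. Partial/part are computed as residual correlations after
  least-squares regression on conditioning spectra; when peaks
  outnumber m/z channels, the *two-step* variants condition only on the
  `q` reference spectra most Pearson-correlated with the query,
  avoiding the singular-covariance problem.
* **Four retention time distances** — Euclidean, Maximum, Manhattan,
  Canberra (self-normalizing per dimension).
* **Five alignment procedures** — PAD (nearest by distance), PAS (most
  similar spectrum), DW-PAS (similarity inside a k-nearest distance
  window), SW-PAD (nearest inside a similarity window at cut-off
  $\rho$), and PAM, which maximizes the mixture score
  $M_d = w/(1 + D_d) + (1 - w)\,S$.
* **An evaluation harness** — TP/FP/FN/TN confusion counts against
  ground-truth pairs, TPR/FPR/PPV/F1, empirical ROC curves with
  trapezoidal AUC (equal to the Mann-Whitney statistic on ties-free
  scores), and same-peak versus different-peak score-distribution
  diagnostics.
* **A synthetic data generator** with known truth, emulating a sparse
  mixture-of-standards regime (~75 compounds/run) and a dense
  biological regime (~450 compounds/run), with shared fragment
  backbones, spectral families, retention-time jitter and
  heteroscedastic spectral noise.
* **A sweep harness and CLI** (`run_sweep()`, `inst/cli/gcxgcalign.R`)
  over the canonical parameter grids.

## Worked example

Generate a dense synthetic run pair (150 compounds, 142 shared), align
it by spectral similarity alone under the two-step partial correlation,
and evaluate against the known truth:

```r
library(gcxgcalign)

cfg  <- synthetic_preset("data2_like", seed = 42,
                         n_compounds = 150, extra_ref = 8)
pair <- generate_run_pair(cfg)
pair$reference
#> <peak_list> run 'sim42_ref' (reference): 150 peaks, 150 labeled
pair$truth
#> <true_pair_set> s = 142 true peak pairs

res <- align_pas(pair$target, pair$reference,
                 similarity_spec("partial", q = 30))
res
#> <alignment_result> pas: u = 142 of n = 142 target peaks matched (m = 150 references)

evaluate_alignment(res, pair$truth)
#> <evaluation_report> TP=114 FP=28 FN=28 TN=21130 | TPR=0.8028 FPR=0.0013 PPV=0.8028 F1=0.8028

alignment_roc(res, pair$truth)
#> <roc_curve> 142 cutoffs, AUC = 0.9010
```

114 of the 142 true pairs are recovered (F1 = 0.80). The same alignment
under Spearman's rank correlation drops to F1 = 0.59 — on dense,
spectrally crowded data the conditioning-based measure wins, because
regressing out the most-correlated reference spectra removes the
fragment backbone and near-duplicate structure that all spectra share:

```r
evaluate_alignment(align_pas(pair$target, pair$reference,
                             similarity_spec("spearman")), pair$truth)
#> <evaluation_report> TP=84 FP=58 FN=58 TN=21100 | TPR=0.5915 FPR=0.0027 PPV=0.5915 F1=0.5915
```

Peak tables, truth files and match lists read and write as plain CSV
(`read_peak_table()`, `write_alignment()`, ...); `run_sweep()` scans
methods x measures x parameters and reports per-combination means and
standard errors across run pairs. A command-line front end wraps the
same functions:

```sh
Rscript inst/cli/gcxgcalign.R simulate --preset data1_like --seed 7 --out-dir sim
Rscript inst/cli/gcxgcalign.R align --reference sim/reference.csv \
    --target sim/target.csv --method pam --measure pearson --w 0.5 --out m.csv
Rscript inst/cli/gcxgcalign.R evaluate --matches m.csv --truth sim/truth.csv \
    --reference sim/reference.csv --target sim/target.csv --out report.csv
```

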