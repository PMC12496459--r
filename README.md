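# serveload

Interpretable prediction of supporting-knee joint load during tennis serves
from bilateral sagittal-plane kinematics.

## What problem this solves

The resultant knee joint moment — the pointwise norm
`M(t) = sqrt(Mx² + My² + Mz²)` of the sagittal, frontal and transverse
moment components — is a standard indicator of knee loading and injury risk
during the serve, but measuring it needs force plates and inverse dynamics.
`serveload` implements, end to end and in pure R, a pipeline that estimates
the full 101-point moment curve of the supporting knee from the six
time-normalized joint-angle curves of both legs (ankle, knee, hip), and
then *explains* the estimate:

* **Representation** — one serve is a fully connected graph of 101 temporal
  nodes, each node carrying the six joint angles of its time point.
* **Model** — three symmetric-normalized graph-convolution layers (64 units,
  ReLU) feed a 64-unit GRU over the node sequence and a shared affine head:
  a GNN-GRU regressor, trained with Adam on the MSE. A standalone GRU on the
  raw features is the baseline, and particle-swarm search is available for
  hyperparameters.
* **Explanation** — layer-wise relevance propagation (epsilon rule;
  gated-signal rule through the GRU) attributes each predicted value back to
  the 101 x 6 inputs, aggregated over the test split and min–max normalized
  to [0, 1] contribution curves per joint.
* **Evaluation** — MAE/MSE/R², pooled-SD Cohen's d, paired t-tests with
  normality pre-check, and one-dimensional statistical parametric mapping
  (SPM) of predicted vs. measured curves with random-field-theory and
  permutation inference.
* **Synthetic world** — since no motion-capture data are deposited with the
  study this emulates, a serve simulator with a *known* per-phase
  angle-to-moment generative mapping stands in, making recovery claims
  testable offline.

Intended users: biomechanics researchers and sports-science methodologists
who want a fully reproducible, inspectable reference implementation of this
model family — including an honest account of where it breaks (see below).

## Worked example

```r
library(serveload)

cfg <- pipeline_config(
  out_dir  = "run",
  seed     = 7,
  simulate = list(n_participants = 12, trials_per_participant = 8),
  model    = list(gcn_width = 32, gru_width = 32, epochs = 150)
)
run_pipeline(cfg)           # simulate -> preprocess -> train -> explain -> evaluate -> report
pipeline_report("run")
```

which prints (abridged, exactly as produced by the run above):

```
== GNN-GRU vs GRU baseline (paired, test split) ==
  mae  GNN-GRU 1.5301 (0.1701) vs GRU 0.4343 (0.0366): t = 18.155, p = 3.805e-07, d = 8.909
  mse  GNN-GRU 5.1905 (1.6714) vs GRU 0.2836 (0.0503): t = 8.269, p = 7.377e-05, d = 4.150
  r2   GNN-GRU 0.7383 (0.0854) vs GRU 0.9857 (0.0026): t = -8.177, p = 7.923e-05, d = 4.097

== Phase-averaged normalized contributions ==
  phase l_ankle l_knee  l_hip r_ankle r_knee  r_hip
1    PP   0.162  0.150 0.0172   0.236  0.248 0.0768
2    FP   0.401  0.101 0.0221   0.496  0.196 0.1151
3    LP   0.308  0.133 0.0131   0.205  0.158 0.0686
```

Reading this: the GNN-GRU reaches R² ≈ 0.74 on held-out serves (96 trials,
150 epochs) while the plain GRU reaches R² ≈ 0.99 — on this representation
the baseline *wins*, decisively and reproducibly. That is a structural
fact, not a tuning accident: on a complete graph the normalized
convolution `D^-1/2 (A+I) D^-1/2 = J/101` maps every node to the feature
column means, so the GCN stack erases temporal identity before the GRU ever
sees the data. The methods vignette
(`vignettes/serveload-methods.Rmd`) derives this and discusses why the
published claim of the opposite direction cannot be architectural. The
contribution table shows which joints the fitted model leans on per serve
phase (Preparation / Flight / Landing), each row normalized to [0, 1]
across the whole curve set.

A command-line wrapper covers the same verbs:

```sh
Rscript inst/cli/serveload pipeline --config cfg.yaml --out run --seed 7
Rscript inst/cli/serveload --version
```

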