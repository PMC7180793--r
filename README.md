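# gaitTDA

Topological analysis of gait stride-interval dynamics for discriminating
healthy from neuro-degenerative walking patterns.

## The problem

The stride interval — the time between consecutive ground contacts of the
same foot — fluctuates from stride to stride, and the *structure* of those
fluctuations changes with neuro-degenerative disease (amyotrophic lateral
sclerosis, Huntington's disease, Parkinson's disease). Classical summary
statistics (mean, variance, fractal exponents) discard the geometry of the
underlying gait dynamics. `gaitTDA` instead characterises each subject's
stride-interval series by the *topology* of its reconstructed phase space
and classifies subjects from those topological summaries.

## The method

For a stride-interval series f(1), …, f(N) (right foot, one walking trial
per subject) the pipeline is:

1. **Cleaning.** Discard the first 20 s of the trial (startup transient).
   Compute the median μ̂ and sample standard deviation s of the remaining
   series once, and replace every stride with value outside
   (μ̂ − 2s, μ̂ + 2s) by μ̂ — these are turn-around artefacts of an
   over-ground walking protocol.
2. **Delay embedding.** Map the series to the 2-D point cloud
   p_t = (f(t), f(t + τ)), t = 1 … N − τ. Quasi-periodic gait rhythm
   traces a loop in this cloud; the delay τ is scanned over {5, 6, 7, 8}.
3. **Maxmin subsampling.** Reduce each cloud to 50 landmarks by greedy
   farthest-point selection, preserving shape at a fixed scale.
4. **Persistent homology.** Build the Vietoris–Rips filtration up to the
   enclosing radius and compute persistence in dimensions 0 and 1 by
   boundary-matrix reduction over Z/2. Each loop contributes a birth–death
   pair (b, d) to the H1 persistence diagram.
5. **Persistence landscapes.** Convert the H1 diagram to landscape
   functions λ_k(x) = k-th largest of min(x − b, d − x)₊ over pairs,
   sampled on a uniform grid (K = 5 levels × G = 100 points), giving a
   500-dimensional feature vector per subject.
6. **Evaluation.** One-vs-one classification (positive class = healthy
   controls) with Gaussian naive Bayes, a depth-5 decision tree, a
   1200-tree random forest, and 3-nearest-neighbours, under leave-one-out
   cross-validation; reports confusion matrices, accuracy, sensitivity,
   specificity (in percent) and rank-based AUC per (τ, classifier).

Wasserstein and bottleneck distances between diagrams (exact
optimal-matching implementations) are included for diagram comparison and
stability analysis, and a synthetic cohort generator produces
gait-dataset-dialect files with controllable loop prominence so the whole
pipeline is testable without any data download.

## Worked example

```r
library(gaitTDA)

s <- generateSubject(defaultProfiles()$HC, seed = 11)
s
#> StrideSeries 'HC_s11' (HC, right foot): 273 strides over 300.0 s, mean 1.103 s

clean <- preprocessSeries(s)                      # trim 20 s, replace outliers
cloud <- maxminSubsample(delayEmbed(clean, tau = 5), m = 50, seed = 42)
cloud
#> PointCloud 'HC_s11': 50 points in 2-D (tau = 5)

dg <- ripsDiagram(cloud)
dg
#> PersistenceDiagram: 50 H0 pairs, 15 H1 pairs (max scale 0.1481)
```

The most persistent H1 pair (birth 0.0197, death 0.0371) is the loop the
quasi-periodic stride rhythm traces in phase space; disease-like profiles
produce weaker, shorter-lived loops. A full two-cohort experiment:

```r
profiles <- defaultProfiles()
hc <- lapply(1:8, function(i) generateSubject(profiles$HC, seed = 100 + i))
pd <- lapply(1:8, function(i) generateSubject(profiles$PD, seed = 200 + i))
res <- runExperiment(hc, pd, tauGrid = c(5, 7), classifiers = c("DT", "KNN"),
                     seed = 42)
head(res, 4)
#>       task tau classifier TP FN FP TN accuracy sensitivity specificity auc
#> 1 HC vs PD   5         DT  8  0  0  8      100         100         100   1
#> 2 HC vs PD   5        KNN  8  0  0  8      100         100         100   1
#> 3 HC vs PD   7         DT  8  0  0  8      100         100         100   1
#> 4 HC vs PD   7        KNN  8  0  0  8      100         100         100   1
```

Each row is one (τ, classifier) configuration: the pooled leave-one-out
confusion matrix, accuracy/sensitivity/specificity in percent, and the
AUC of the pooled scores; rows are sorted by AUC. The synthetic healthy
and parkinsonian profiles are built to be separable, and the topological
features recover that separation perfectly here.

A command-line front end wrapping the same functions is installed at
`system.file("exec", "gaitTDA.R", package = "gaitTDA")` with `simulate`,
`extract` and `experiment` subcommands.

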