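# resdyn — residual dynamics of task-evoked EEG

How quickly does neural activity return to its mean trajectory after a
perturbation, and how does that change across adolescence? `resdyn`
implements an analysis that answers this from multichannel EEG recorded
during a Flanker task: trial-averaged ERPs are projected into a
two-dimensional principal-component state space, trial-by-trial *residuals*
around the condition means

x<sub>ijt</sub> = s<sub>ijt</sub> − s̄<sub>jt</sub>

are modelled with a moving-window first-order autoregression

x<sub>t+1</sub> = A<sub>t</sub> x<sub>t</sub> + ε<sub>t</sub>,

and the eigenvalue moduli of each window's 2×2 matrix A<sub>t</sub> index
the temporal persistence of perturbations: λ near 1 = slow decay (shallow
attractor), λ near 0 = fast return to the mean trajectory. Around this core
sit the behavioural measures (accuracy, reaction time, Balanced Integration
Score), time-resolved mixed-effects statistics with FDR correction over
time, cluster averaging, Bonferroni post hocs, and bootstrap mediation
(age → λ → performance; institutionalization → λ → performance) with BCa
intervals.

The package is written for a longitudinal three-group design (never-
institutionalized, foster-care, care-as-usual; ages 12/16/21) and ships a
synthetic-cohort generator with known ground-truth dynamics — an adaptive
staircase Flanker simulator plus latent AR(1) EEG — so the whole chain is
testable end to end without access to any real recordings. Who it is for:
researchers who want the dynamical-systems statistic itself, and anyone who
needs a fully auditable reference implementation of the pipeline.

## Worked example

A reduced cohort (4 participants per group) through the whole pipeline:

```r
library(resdyn)
cfg <- generator_config(n_per_group = c(NIG = 4, FCG = 4, CAUG = 4), seed = 7)
results <- run_all(pipeline_config(generator = cfg, n_boot = 1000), progress = FALSE)

results$space
#> State space: 56 channels -> 2 PCs; PC1+PC2 explain 99.5% of variance

head(subset(results$eigen_table, alignment == "flanker" & pid == "P001" & age == 12), 3)
#>   t_center   lambda1   lambda2   ok  pid age group alignment
#> 1  -0.9125 0.7393685 0.5724249 TRUE P001  12   NIG   flanker
#> 2  -0.8875 0.7451613 0.6049769 TRUE P001  12   NIG   flanker
#> 3  -0.8625 0.7265181 0.6086684 TRUE P001  12   NIG   flanker

round(with(results$cluster_means[["lambda1.flanker.age_f"]], tapply(lambda1, age, mean)), 3)
#>    12    16    21
#> 0.772 0.732 0.683

results$mediation[["lambda1.flanker.age_f"]]$age
#> Mediation (n = 36, 1000 bootstrap draws, 95% BCa CIs):
#>        estimate    lower    upper
#> a       -0.0100  -0.0147  -0.0050
#> b      -17.0114 -20.4646 -14.4161
#> cprime  -0.1695  -0.2247  -0.1150
#> ab       0.1695   0.0898   0.2524
#> c        0.0000  -0.0917   0.0883

round(results$recovery$rmse_lambda1, 3)
#> [1] 0.023
```

Reading the numbers: the two shared principal components capture
essentially all grand-ERP channel variance; the first eigenvalue's
cluster-averaged trajectory *decreases* with age (0.772 → 0.683), i.e.
perturbations die out faster in older participants; age lowers λ (path a
< 0) and lower λ predicts better performance (path b < 0), so the indirect
effect a×b on the Balanced Integration Score is positive and its BCa
interval excludes zero. (The total effect c is ~0 here because BIS is
standardized within age; the decomposition into indirect and direct paths
is still identified.) The recovered eigenvalue series track the
generator's ground truth to an RMSE of 0.02.

## The analysis, as shipped

The numbered drivers under `analysis/` run the study-scale workflow and
write their tables under `results/` (`--small` runs a 9-participant
version):

| driver | what it does |
|---|---|
| `01_simulate.R` | build the cohort, event tables, ground truth |
| `02_preprocess.R` | full-rate filter chain demo + path-equivalence check |
| `03_statespace.R` | condition ERPs → grand matrix → PCA space |
| `04_dynamics.R` | residuals → windowed AR(1) → eigenvalue series + recovery audit |
| `05_behavior.R` | accuracy / RT / BIS |
| `06_stats.R` | timewise LMEs, FDR, clusters, post hocs, mediation |
| `07_report.R` | one-shot `run_all()` + markdown report |

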