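# wfgica

Group spatial ICA and brain-state statistics for wide-field calcium imaging.

Wide-field (mesoscale) calcium imaging films the fluorescence of the whole
dorsal cortex of a mouse at tens of Hz. As the brain state is moved with
graded isoflurane anesthesia — from deep burst suppression through
oscillatory intermediate levels to wakefulness — the spatial organization of
cortical activity reorganizes. `wfgica` decomposes multi-subject,
multi-session recordings into spatial independent components (ICs) that are
shared across the group, and quantifies how each component's activity and
the co-activation structure between components depend on the brain state.
It is written for imaging labs analyzing state-dependent mesoscale dynamics,
and it ships a ground-truth synthetic study generator so the entire chain is
testable end to end.

## The method in brief

For sessions `s = 1..M` with preprocessed data `Y_s` (`T_s x P` pixels,
percent dF/F0, 0.1 Hz high-passed, states concatenated deepest-to-awake):

1. **Two-stage reduction.** Temporal PCA per session, `Y_s ~ G_s X_s` with
   whitened `X_s` (`L1 x P`), then group PCA of the stacked `X_s` to `K`
   dimensions, `X ~ Ghat X_w`.
2. **Spatial ICA.** FastICA (logcosh, symmetric decorrelation) on `X_w`,
   stabilized with ICASSO: the ICA is re-run under random initialization
   and pixel bootstrap, estimates are clustered by `|r|`, and each
   cluster's centrotype becomes a component. The model order `K` is chosen
   by minimizing an R-index (cluster compactness/separation ratio) over
   candidate orders.
3. **Back-reconstruction.** Per-session maps and time courses via the GICA
   chain: `R_s = G_s Ghat_s A`, `S_s = pinv(Ghat_s A) X_s`.
4. **Annotation.** Each IC is tagged by the atlas macro area under its peak
   |weight| pixel; midline-confined and vessel-like (elongated) components
   are flagged and excluded.
5. **Occurrence statistics.** Per IC and session, a binary activation
   vector marks frames beyond `mean ± 3 sd` of the deepest-state (iso 2%)
   time course; `N[IC, ST]` counts suprathreshold frames and
   `N[IC, ST] / sum_IC N[IC, ST]` is the IC's relative occurrence in state
   `ST`. A bootstrap null (5,000 resampled crossings from the deepest state
   + 5,000 from awake) gives each IC's expected proportion; an IC is
   *prominent* when the lower bound of its across-subject 95% CI exceeds it.
6. **Co-occurrence.** Pearson correlation between binary vectors (the phi
   coefficient) per IC pair, state and session; Fisher-z averaged within
   macro groups.
7. **State tests.** One-way repeated-measures ANOVA over the six states
   (`F(s-1, (s-1)(n-1))`) and Holm-corrected paired t post hocs.

## Worked example

```r
library(wfgica)

# a compact synthetic study: 3 subjects x 2 sessions, six anesthesia states
study <- simulate_study(height = 40, width = 40, fps = 10,
                        dur_per_state = 120, seed = 1)
res <- analyze_study(study, k = 8, n_runs = 5, seed = 1)

summary(res$fit, atlas = study$atlas)
#> Group ICA: 8 components over 6 sessions; R-index 0.1218
#>  ic peak_row peak_col stability             group
#>   1       20        7     1.000     Somatosensory
#>   2       20       34     1.000     Somatosensory
#>   3       10       13     1.000       Somatomotor
#>   4       32       11     1.000            Visual
#>   5       30       17     0.998     Retrosplenial
#>   6       23       26     0.999 PosteriorParietal
#>   7       10       28     1.000       Somatomotor
#>   8       30       24     0.999     Retrosplenial

res$occurrence
#> Relative occurrence by macro group (subject means):
#>              group  awake iso0.5 iso1.0 iso1.5 iso1.75 iso2.0
#>  PosteriorParietal 0.1092 0.1096 0.1122 0.1045   0.118  0.119
#>      Retrosplenial 0.0281 0.0415 0.0539 0.0895   0.109  0.140
#>        Somatomotor 0.1803 0.1799 0.1714 0.1469   0.133  0.120
#>      Somatosensory 0.1695 0.1620 0.1505 0.1440   0.136  0.123
#>             Visual 0.1349 0.1237 0.1362 0.1347   0.127  0.117

res$anova_occurrence
#> RM ANOVA: F(5, 10) = 97.362, p = 3.779e-08
```

Reading the output: all eight planted sources are recovered as stable ICs
(`stability` is the mean within-cluster similarity across ICASSO runs) and
tagged with the correct macro areas. The occurrence table shows the
retrosplenial group's share of significant activations falling
monotonically from 0.140 under 2% isoflurane to 0.028 awake — the
generator's designed trend — while sensorimotor groups rise; the
repeated-measures ANOVA over the six states confirms the state dependence
with the `(5, 10)` degrees of freedom of a 6-state x 3-subject design.
Co-activation between the two retrosplenial ICs behaves the same way:

```r
round(pair_phi(res), 2)
#>  iso2.0 iso1.75  iso1.5  iso1.0  iso0.5   awake
#>    0.87    0.79    0.69    0.54    0.50    0.45

evaluate_recovery(res$fit, study)$mean_abs_r
#> [1] 0.979
```

`run_pipeline(config, out_dir)` runs the same chain from a (YAML)
configuration and writes every stage product — labels, occurrence and
co-occurrence tables, ANOVA/post hoc CSVs, the bootstrap null, and a
manifest with seeds and the config hash — to a directory, reproducibly.

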