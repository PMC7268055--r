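# longconn

Longitudinal analysis of weighted brain connectivity networks in a
two-group, repeated-measures design — for neuroimaging researchers who have
per-subject connectivity matrices (functional: ROI-pairwise BOLD
correlations; structural: streamline-count weights on an AAL-90-style
parcellation) across several timepoints and want the full chain from
matrices to group-level inference:

- **Weighted topology metrics** with disconnection-safe harmonic means:
  nodal strength *S<sub>i</sub>* = Σ<sub>j</sub> w<sub>ij</sub>, nodal
  efficiency *E<sub>i</sub>* = (N−1)<sup>−1</sup> Σ<sub>j≠i</sub>
  1/L<sub>ij</sub>, shortest-path betweenness *B<sub>i</sub>* and its
  normalized form *b<sub>i</sub>* = *B<sub>i</sub>*/⟨*B*⟩, network strength
  *S<sub>net</sub>* = N<sup>−1</sup> Σ *S<sub>i</sub>*, and the harmonic
  characteristic path length
  *L<sub>net</sub>* = [ (N(N−1))<sup>−1</sup> Σ<sub>i</sub>Σ<sub>j≠i</sub> 1/L<sub>ij</sub> ]<sup>−1</sup>,
  where edge lengths are reciprocal weights. Small-world indices
  (γ, λ, σ) against degree-preserving rewired null ensembles.
- **Proportional density thresholding** (exact edge counts, deterministic
  tie-breaks, nested sweeps; functional 0.05–0.20 and structural 0.05–0.15
  grids by default) with area-under-curve summaries.
- **Functional–structural coupling**: Pearson correlation between
  rank-Gaussianised (Blom normal scores) nonzero structural edge weights
  and the raw functional values at the same edges.
- **Group × time inference**: mixed-design repeated-measures ANOVA
  (between: group; within: time), post-hoc two-sample t and within-group
  RM-ANOVA tests, the 1/*n* false-positive family adjustment (1/90 = .011
  for a 90-node parcellation), change-score Pearson correlations, and
  seed-reproducible permutation tests (exact by enumeration at small n).
- **Split-half reproducibility**: covariate-matched cohort halvings, mean
  connectivity pattern correlations, and permutation comparisons of global
  metrics.
- **A synthetic study generator** — small-world substrates, paired SC/FC
  matrices with tunable coupling, group-specific nodal deficits that
  partially recover over follow-up — so the entire pipeline is testable
  end-to-end without any patient data.

Everything is tibble-first and pipe-friendly; fitted ANOVA objects support
`tidy()`/`glance()`/`autoplot()`, and `plot_metric_trajectories()`,
`plot_coupling()`, `plot_density_sweep()` cover the standard figures.

## Worked example

Simulate a study at the design's size (21 patients, 17 controls, 3
timepoints, 90 nodes; patients carry a 50% edge-weight deficit at 5 nodes
that recovers to 50% then 80% over follow-up), and test the planted effect:

```r
library(longconn)
library(dplyr)

cfg   <- simulation_config(seed = 2024)
study <- generate_study(cfg)
study
#> <lc_study: 21 patients + 17 controls x 3 timepoints, 90 nodes, 228 matrices>

aff <- study$ground_truth$affected_nodes   # 8 22 26 33 54

si <- purrr::map_dfr(
  study$matrices[grepl("structural", names(study$matrices))],
  \(m) tibble::tibble(subject_id = m$subject_id, group = m$group,
                      timepoint = m$timepoint,
                      si = mean(rowSums(m$weights)[aff])))

fit <- rm_anova(si, si, subject_id, group, timepoint)
fit
#> Mixed-design RM-ANOVA: 38 subjects (control n=17, patient n=21), 3 timepoints
#>      effect df df_error         F            p
#>       group  1       36  852.2304 1.172897e-26
#>        time  2       72 2446.2161 6.496281e-67
#>  group:time  2       72 2050.1245 3.393451e-64
#> Greenhouse-Geisser epsilon: 0.893
```

The implanted deficit shows up exactly as designed: a huge group main
effect (patients' affected-node strength is depressed), a time effect and a
group × time interaction (patients recover across timepoints while controls
stay flat) — all far below the 90-node family threshold
`false_positive_adjust(90)` = 0.0111.

Per-subject coupling, and topology of one thresholded network:

```r
coupling_table(study$matrices) |> head(3)
#>   subject_id group   timepoint     r n_edges
#> 1 pat01      patient baseline  0.831     601
#> 2 pat01      patient 1-month   0.827     601
#> 3 pat01      patient 6-month   0.835     601

tn <- threshold_to_density(study$matrices[["pat01_baseline_structural"]], 0.10)
network_metrics(tn$net, small_world = TRUE, n_nulls = 50, seed = 1)$global
#>   strength char_path_length clustering gamma lambda sigma
#> 1     13.6             1.40     0.0641  4.35   1.10  3.95
```

σ ≈ 4 ≫ 1: the simulated substrate is small-world, as the analysis assumes.
The whole pipeline (metrics sweep → coupling → ANOVA + post hoc →
reproducibility → change scores), writing one long-format CSV per stage
plus a run summary, is:

```r
rc <- run_config(out_dir = "results/run1", seed = 7)
run_pipeline(rc, study = study)
```

A thin command-line wrapper (`inst/cli/longconn.R`) exposes `simulate` and
`run` subcommands over the same functions. See the vignette
(`vignettes/longitudinal-connectome-analysis.Rmd`) for the methods in full.

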