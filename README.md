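# cmpunit

Single-unit spike-train analysis of the **constructive memory-perception
(CMP) task** — a primate paradigm in which an item cue triggers retrieval
of a learned item–location association and a subsequently presented,
randomly rotated background image determines where that remembered
location now lies on screen.  The package is for systems neuroscientists
who want a tested, reusable implementation of the task's complete
single-unit analysis chain, together with a synthetic spike-train
generator with ground-truth neuron archetypes so every statistic can be
validated without the original recordings.

## What it computes

Eight items (sets A and B) are pairwise assigned to four co-locations
I–IV on the background; the saccade target is the cued co-location
carried with the rotated background,

```
target = (default_angle[c] − θ) mod 360 .
```

On top of that geometry the package implements:

- **Classification screens** — per-neuron sliding-window (8 × 300 ms)
  one-way ANOVA over the 8 item cues, and a three-way *nested* ANOVA
  (co-location 3 df, background orientation 2 df, target 3 df, items
  nested under co-locations 4 df; sum-to-zero coding, Type-III-like
  model comparison) at family level *P* < 0.01 with Bonferroni
  correction over windows, plus dense 100-ms/1-ms instantaneous *F*
  time courses.
- **Co-location index** — per significant window, Pearson *r* between
  the responses to the set-A and set-B items ordered by co-location
  (4 pairs, df = 2); Fisher-*Z* averaged across windows,
  back-transformed, with a trial-shuffle permutation test (two-tailed,
  add-one corrected).
- **ROC discriminability** — AUC (Mann–Whitney with ties at ½) between
  optimal and paired items, and best co-location versus the rest, with
  the re-determination permutation null (the higher-mean partition is
  relabeled "optimal" at each shuffle, so the null median exceeds 0.5).
- **Construction analyses** — orientation-tuning similarity across
  co-locations (convergence), the matching index over the three
  rotation patterns (default-orientation coding), and best-minus-other
  normalized population SDFs split by background orientation
  (transference vs targeting).
- **Error analysis** — partial correlations of error-trial rates with
  the correct-trial rate templates of the chosen versus the missed
  target position, Fisher-averaged over qualifying bins.
- **Synthetic sessions** — inhomogeneous-Poisson neurons from eight
  archetypes (untuned, unitized/non-unitized item coding, background,
  convergent, transferring, targeting, multiphase) with configurable
  unitization and choice-versus-instruction weighting, plus CSV session
  I/O that re-validates every task invariant on load.

See `vignettes/cmp-analysis-methods.Rmd` for the full account of the
models, thresholds and design choices.

## Worked example

```r
library(cmpunit)
spec <- session_spec(counts = c(item_unitized = 4, targeting = 4, untuned = 4),
                     n_trials = 128, seed = 1)
ses <- simulate_session(spec)
print(ses)
#> CMP session: 12 neurons, 128 trials (85.9% correct), 22703 spikes

scr <- screen_neurons(ses)
table(archetype = ses$truth$archetype, item_selective = scr$item_icue)
#>                item_selective
#> archetype       FALSE TRUE
#>   item_unitized     0    4
#>   targeting         0    4
#>   untuned           4    0

ca <- colocation_analysis(ses, 1, n_perm = 1000, seed = 1)
#> neuron 1 co-location index r = 0.95 (p = 0.0020, permutation, 2-tailed)

ra <- roc_analysis(ses, 1, n_perm = 1000, seed = 1)
#> optimal (I-A) vs pair (I-B): AUC = 0.66, p = 0.17
#> best co-location vs others:  AUC = 0.94, p = 0.0010
```

The unitized neuron shows the characteristic pattern: a near-ceiling
co-location index, no significant discrimination between the two items
sharing its co-location, but strong discrimination of that co-location
from the others.  (Targeting neurons are also item-selective during the
item-cue period because their preferred target coincides with one
co-location's default-orientation position.)

## The analysis workflow

Numbered drivers under `analysis/` run the pipeline stage by stage on a
synthetic session configured in `analysis/config.yaml` (profiles:
`ci` ≈ 1 min, `full` = recorded 456-neuron scale):

```sh
Rscript analysis/01_simulate.R      # session + ground truth -> results/session/
Rscript analysis/02_screen.R       # ANOVA screens, category counts, truth recovery
Rscript analysis/03_indices.R      # co-location index + ROC permutation tests
Rscript analysis/04_construction.R # tuning similarity, matching index, target SDFs
Rscript analysis/05_errors.R       # error-trial partial correlations
Rscript analysis/06_report.R       # summary tables and run manifest
```

`run_pipeline(default_config("ci"))` does the same in one call.

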