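# orflow

Interaction-based surgical workflow segmentation from operating-room staff
movement trajectories.

## What this is for

During a neurosurgery, who is cooperating with whom changes from phase to
phase: the surgeon and scrub nurse work hand-in-hand during craniotomy and
tumor resection, barely at all during preparation and wrap-up. `orflow`
turns indoor-positioning tracks of the four OR staff roles (surgeon,
assistant nurse, scrub nurse, anesthetist) into exactly that signal and
uses it to classify the six phases of an intraoperative-MRI neurosurgery
— Preparation, Craniotomy, Close, MRI, TR (tumor resection), End. It is
aimed at surgical data-science work where positioning data exist but
video/signal annotation does not.

The pipeline:

1. **Movement**: read/resample 1 Hz trajectories, slice them into phase
   segments, summarize activity (step-distance = speed distributions by
   role and phase).
2. **Interaction**: for each phase segment and role pair, the
   longest-common-subsequence (LCSS) trajectory similarity

   S(A,B) = LCSS_{ε,δ}(A,B) / min(|A|,|B|) ∈ [0,1],

   where points match if within ε mm (default 500) and δ samples
   (default 5). With 4 roles this gives the 4 × 4 = 16 interaction kinds
   per segment; four pairs are kept as model attributes and discretized
   into Low/Medium/High tertiles.
3. **Model**: a discrete Bayesian network over {phase, 4 interaction
   levels}: P(X₁,…,Xₙ) = ∏ᵢ P(Xᵢ | Parents(Xᵢ)), structure learned by
   score-based hill climbing (BIC default; AIC/BDeu/log-likelihood
   available), maximum-likelihood CPTs with Laplace smoothing, exact
   posterior inference by variable elimination, classification by
   posterior argmax. A naive Bayes baseline shares all of this machinery.
4. **Validation**: repeated random holdout (default 40 training segments,
   1000 repetitions), with discretization, structure, and parameters all
   refit inside every training split.

Because the original clinical recordings are not publicly available, the
package includes a synthetic OR simulator (`generate_dataset()`): a
5.8 × 4.8 m room, role-specific activity zones, 80 mm tracking noise,
phase-dependent rendezvous-based cooperation, and role absences (the
scrub nurse rarely appears during Preparation). Ten simulated cases yield
83 phase segments by default.

## Worked example

```r
library(orflow)

cfg <- or_sim_config()                       # the default study conditions
ds  <- generate_dataset(cfg, n_cases = 10, seed = 7, target_segments = 83)
tab <- build_feature_table(ds, params = lcss_params(eps = 500, delta = 5),
                           resample_first = FALSE)

aggregate(surg_scrub_sim ~ phase, tab, mean)
#>         phase surg_scrub_sim
#> 1 Preparation          0.022
#> 2  Craniotomy          0.367
#> 3       Close          0.321
#> 4         MRI          0.196
#> 5          TR          0.430
#> 6         End          0.152
```

Mean surgeon–scrub similarity is highest in TR and Craniotomy and lowest
in Preparation and End — the cooperation pattern the phases are read
from. Learning the full-data network over discretized levels:

```r
lev <- tab[, "phase", drop = FALSE]
for (p in names(default_pairs())) {
  disc <- discretize_fit(tab[[paste0(p, "_sim")]])
  lev[[paste0(p, "_level")]] <- discretize_apply(disc, tab[[paste0(p, "_sim")]])
}
hill_climb(lev, score = "bic")$dag
#> <or_dag> 5 node(s), 4 edge(s)
#>   asst_surg_level -> phase
#>   phase -> surg_scrub_level
#>   phase -> anes_asst_level
#>   surg_scrub_level -> asst_scrub_level
```

The phase is directly tied to the surgeon–scrub channel, with the
assistant-nurse pairs influencing it — a semantic summary of
who-works-with-whom per phase. Validating by repeated holdout:

```r
cmp <- compare_classifiers(tab, n_train = 40, n_reps = 200, seed = 7)
cmp
#> <or_comparison>
#>   bn   mean 0.493  range [0.256, 0.698]
#>   nb   mean 0.493  range [0.256, 0.698]
```

Both classifiers sit near 0.49 against a 1/6 ≈ 0.17 chance floor, with
the network and naive Bayes effectively tied on these conditions (at 40
training rows the BIC search adds no attribute–attribute edges beyond the
augmented-naive backbone, so the two models coincide; see the methods
vignette for why the classifier default augments the structure).

A command-line wrapper covering the same pipeline ships in
`inst/cli/orflow.R`:

```sh
Rscript inst/cli/orflow.R run-all --cases 10 --seed 7 --out out/
```

## File formats

* Tracks: CSV `case_id,role,tag_id,t,x,y,z` (seconds since case start,
  millimetres).
* Phase intervals: CSV `case_id,phase,t_start,t_end`, half-open
  `[t_start, t_end)`.
* Feature tables: CSV `case_id,occurrence,phase,<pair>_sim,…` with
  optional `<pair>_level` columns.
* Networks: JSON (nodes/states, edges, CPTs), exact round trip.

Writers and readers for all four live in the package.
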