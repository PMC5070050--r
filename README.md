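# dyadsync

Motion and synchrony features from dual 3D skeleton recordings of dyadic
interaction.

## What this is for

Researchers studying early mother-infant interaction (and dyadic behaviour
more broadly) film short free-play sessions and have experts rate them with
global instruments such as the Coding Interactive Behavior (CIB). `dyadsync`
implements the computational counterpart: given two synchronized RGB-D
skeleton streams — one sensor facing each partner — it co-registers the
sensors in space (rigid least-squares from corresponding calibration points)
and time (cross-correlation of clap/energy envelopes), and extracts a
canonical 17-element vector of individual and dyadic motion features per
session. It then provides the statistics used to validate such features
against observer ratings and clinical group labels.

The 17 features, for a session sampled at rate *1/Δt* with joint positions
*p_j[i]*:

* per-partner **quantity of movement** `q[i] = Σ_j ‖p_j[i] − p_j[i−1]‖/Δt`
  (head + hands), session mean and SD;
* per-partner **motion activity ratio**: fraction of time in the moving
  state after thresholding `q` (0.05 m/s) and removing bouts/pauses shorter
  than 0.25 s by morphological closing/opening;
* **inter-head distance** mean and SD, and each partner's **contribution
  share** to its change (projection of each head's displacement on the
  inter-head axis, accumulated in absolute value, normalized to sum to 1);
* **face-to-face ratio** (both partners' head orientations within 30° of
  each other's head) and per-partner **task-orientation ratio** (within 30°
  of the task point);
* directed **synchrony ratios**: fraction of one partner's movement onsets
  answered by the other within 3 s (`sync_parent_to_infant` = parent
  answering infant);
* **overlap ratio** (both moving) and **pause ratio** (both still); with
  discordant time these partition the session exactly.

Validation statistics: Spearman rank correlation of each feature with each
of the eight CIB composites, Holm step-down correction per composite family;
exact Mann-Whitney and Fisher tests for group comparisons; and a linear SVM
with seeded, stratified k-fold cross-validation (default k = 15) for
group classification.

Because clinical recordings cannot be redistributed, the package includes a
seeded synthetic-dyad generator (two-state Markov movement dynamics, planted
onset coupling, configurable gaze behaviour, tracking dropout) with full
ground truth, plus cohort presets and a parameter-to-composite link model so
the entire pipeline is testable end to end.

## Worked example

```r
library(dyadsync)

# a 4-minute synthetic session at 30 Hz with moderate mother-response coupling
cfg <- dyad_sim_config(p_resp = 0.6, seed = 42)
sim <- simulate_dyad(cfg)
sim$recording
#> <dyad_recording> 7201 frames @ 30 Hz (240.0 s), frame=common

extract_feature_vector(sim$recording, session_id = "demo")
#> <motion_feature_set> session demo
#>           mother_qom_mean             mother_qom_sd           infant_qom_mean
#>                    0.2857                    0.2123                    0.2302
#>             infant_qom_sd     mother_activity_ratio     infant_activity_ratio
#>                    0.2156                    0.5994                    0.4702
#>       heads_distance_mean         heads_distance_sd mother_heads_contribution
#>                    0.7989                    0.0800                    0.5385
#> infant_heads_contribution        face_to_face_ratio         mother_task_ratio
#>                    0.4615                    0.1043                    0.3568
#>         infant_task_ratio     sync_parent_to_infant     sync_infant_to_parent
#>                    0.4499                    0.8393                    0.6462
#>             overlap_ratio               pause_ratio
#>                    0.2998                    0.2325
```

Reading the output: both partners move roughly half the time
(`*_activity_ratio`; the infant's two-state dynamics have stationary moving
probability 0.45, and the measured 0.470 tracks this session's realized
value). Heads sit ~0.80 m apart across the table and contribute almost
equally to distance changes. The parent answers 84% of infant movement
onsets within 3 s — the planted coupling (0.6) plus the chance rate at which
an independently moving mother would onset inside a 3 s window. Overlap
(0.30) + pause (0.23) + discordant time sum to 1.

For a whole cohort with rated composites and group labels:

```r
coh <- simulate_cohort(10, seed = 7)          # 10 low-risk + 10 high-risk dyads
feats <- lapply(seq_along(coh$recordings), function(s)
  extract_feature_vector(coh$recordings[[s]], session_id = coh$session_ids[s],
                         group = coh$labels[s]))
X <- read_feature_table(write_feature_table(feats, tempfile(fileext = ".csv")))
run_validate(X, coh$cib, k = 15, seed = 7)
```

which prints the Holm-corrected feature-composite correlations and the
cross-validated classification accuracy.

Raw sensor data enter through session directories
(`mother.csv`/`infant.csv` skeleton files, optional `calibration.csv` and
`sync_*.csv`), processed end to end by `run_extract()`; a thin command-line
front end with `simulate` / `extract` / `validate` subcommands lives at
`inst/cli/dyadsync.R`.

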