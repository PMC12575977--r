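# fintrack3d

Camera-based 3D fish–object distance estimation for aquaculture.

Farmed fish tend to keep their distance from intrusive objects (vehicles,
cleaning robots, instrumentation) placed inside net pens, and that avoidance
distance is a welfare-relevant behavioural signal. Measuring it in real time
from a small on-structure camera rig — rather than a slow sweeping sonar — is
the problem this package addresses. It is aimed at researchers in fish
behaviour and underwater robot perception who have per-frame detector /
segmenter / matcher / depth-model outputs (the neural networks themselves are
*pluggable backends*, not part of this package) and want tested, reproducible
geometry, tracking, association and statistics on top of them.

## What it implements

Four pipelines over a rectified stereo rig (baseline `b` mm, focal lengths
`fx, fy`, principal point `(cx, cy)`), all emitting one record schema
(`frame, track_id, X, Y, Z, distance_m`):

* **segmentdepth** — caudal-fin boxes detected in both views, masks segmented
  within them, cross-view association by mask IOU + Hungarian assignment,
  triangulation of mask centroids (a `match_on = "bbox"` variant matches on
  boxes but keeps mask centroids);
* **bboxdepth** — association and triangulation on the boxes themselves;
* **superglue** — sparse feature matches filtered to confidence > 0.1 and to
  points inside tracked boxes; the right-image position of the box centre is
  estimated by the offset-vector construction and triangulated;
* **mono** — a metric depth raster is read at the tracked box centre and
  back-projected (single camera, no stereo consistency check).

Triangulation follows the pinhole model

```
Z = b·fx / (xl − xr),   X = Z·(u − cx)/fx,   Y = Z·(v − cy)/fy
```

with the baseline in mm and output in meters. Multi-object tracking is a
ByteTrack-style two-stage IOU association (high-confidence stage with lost
track recovery, low-confidence rescue stage, buffer-limited track removal).
A synthetic stereo fish-scene simulator (correlated-random-walk fish,
projected elliptical fins, detection dropout, pixel noise, oracle masks /
matches / z-buffer rasters, full ground truth) makes every pipeline testable
without field video. Evaluation statistics: per-frame closest-fish distance,
per-case mean ± sd across replicates, MAE with a Student-t 95% CI against an
independent (e.g. sonar) reference, depth-based ranking of individuals, and
Savitzky–Golay trajectory smoothing.

## Worked example

```r
library(fintrack3d)

cfg   <- scene_config(n_fish = 3, n_frames = 100, seed = 1)   # 42 mm baseline rig
scene <- render_observations(simulate_trajectories(cfg))
scene
#> fin_scene: 3 fish, 100 frames, 501 detections, 2620 matches (seed 1)

rec <- run_segmentdepth(scene)
rec
#> fin_trajectories [segmentdepth]: 235 records, rejections: no_match=15
#>   disparity=0 range=0 bounds=0 empty_mask=0 nonfinite_depth=0

head(min_distance_series(rec), 3)
#>   frame min_dist
#> 1     0 3.663154
#> 2     1 2.769564
#> 3     2 2.593785

summarize_case(min_distance_series(rec), case_label = "sim")
#> case sim: 2.034 +/- 0.540 m (100 frames, 1 replicates)
```

The 235 records are 3D fin positions (left-camera frame, meters) with stable
track identities; the per-frame minima are the closest-fish distance series,
and the case summary is its pooled mean ± sd. At the default noise level
(0.5 px) the median depth error against the simulator's ground truth is
about 0.04 m. The packaged example tables (per-case distances of the four
pipelines and the sonar reference; per-individual depth estimates for one
frame) reproduce the published headline statistics:

```r
tab <- example_case_table()
mae_with_ci(tab$segmentdepth_mean, tab$reference_mean)
#> MAE 0.205 m, 95% CI (0.050, 0.360), n = 6

r <- rank_depths(data.frame(id = example_depth_table()$id,
                            depth = example_depth_table()$segmentdepth))
r$closest ; r$furthest
#>    id depth rank        |     id depth rank
#> 1 685 0.678    1        |  9 628 3.748    9
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "fintrack3d", package = "fintrack3d"))')
Rscript $CLI simulate --config scene.json --out scene/        # fixture bundle
Rscript $CLI run --pipeline segmentdepth --scene scene/ --out out/
Rscript $CLI eval --trajectories cases/ --reference ref.csv --out report.json
```

`simulate` writes MOT-style detection CSVs per side, mask JSON, match CSV,
ground-truth CSV, calibration JSON and a manifest; `run` writes a trajectory
CSV and a JSON run summary with per-stage rejection counts; `eval` aggregates
trajectory files named `<CASE>_<replicate>.csv` into per-case summaries and
an MAE report against a `case,mean_m` reference CSV.

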