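# iplmotion

Simulation of how intrafraction prostate motion degrades the dose coverage
of spherical boosts on intraprostatic lesions.

Dose escalation to a dominant intraprostatic lesion (IPL) is delivered as a
simultaneous integrated boost (SIB): a small high-dose sub-volume inside
the prostate treatment plan.  After image-guided setup the prostate keeps
drifting during the fraction, so a lesion of radius 3–7 mm can move partly
out of its boost.  `iplmotion` quantifies that loss for medical physicists
and radiation oncologists exploring margin choices: it simulates tracked
displacement trajectories, evaluates closed-form sphere-overlap coverage
for every recorded displacement, and estimates dose–volume histograms by
Monte Carlo.

## The model

The IPL is a sphere of radius *r*; the boost dose is constant inside a
concentric sphere of radius *r + m* (safety margin *m*) and zero outside.
A displacement of Euclidean length *d* separates the two sphere centres,
and their lens-shaped intersection has closed-form volume

    V_overlap = π/(12 d) · (2r + m − d)² · (d² + 2d(2r + m) − 3m²),   m < d < 2r + m,

with V = 4πr³/3 for d ≤ m and V = 0 for d ≥ 2r + m.  Normalizing by the
lesion volume gives the lesion coverage c_IPL; normalizing by the boost
volume gives the dose efficiency c_SIB, with the exact identity
c_SIB = r³/(r+m)³ · c_IPL.  Motion is modelled per axis as Brownian motion
with drift — displacement variance grows linearly in elapsed time, the
signature of intrafraction drift — with log-normal between-patient
motility multipliers.  DVHs are estimated from 5000 points sampled
uniformly in the lesion sphere, each tested against every displaced boost
sphere.

## Worked example

```r
library(iplmotion)

params <- motion_model_params(seed = 20190516L)  # 28 patients x 26 fractions
ts <- simulate_cohort(params)                    # 39,312 samples

displacement_table(ts)
#>    statistic longitudinal lateral vertical radial
#>  1 mean           -0.162   0.0135   0.153   1.56
#>  2 std             1.08    0.652    1.44    1.12
#>  ...
#>  8 q95             1.46    1.08     2.63    3.71
#> 10 rms             1.09    0.652    1.44    1.92
```

The pooled cohort drifts ~1.6 mm radially on average and stays within
3.7 mm 95% of the time; lateral motion is the quietest axis and vertical
the largest, as in tracked cohorts.

```r
coverage_percent_table(ts, which = "c_sib")
#>   statistic m0_r3 m0_r5 m0_r7 m2_r3 m2_r5 m2_r7 m5_r3 m5_r5 m5_r7
#> 1 mean         64    77    83    21    36    46     5    12    20
#> 6 median       67    80    86    22    36    47     5    13    20
#> 9 max         100   100   100    22    36    47     5    13    20
```

Each column is one margin/radius combination (`m2_r5` = 2 mm margin,
5 mm lesion).  The maximum rows under nonzero margins are pure geometry —
r³/(r+m)³, e.g. 36% for `m2_r5` and 20% for `m5_r7` — so even a perfectly
centred lesion receives just over a third of the boost dose bath at a 2 mm
margin: margins buy coverage at a steep price in dose efficiency.

```r
pts <- sample_sphere(5, n = 5000, seed = 1)
curve <- compute_dvh(pts, ts, sphere_geometry(5, 2))
dvh_query_D(curve, 0.80)  # 0.962: 80% of lesion volume gets >= 96% dose
dvh_query_V(curve, 0.95)  # 0.889: 89% of volume gets >= 95% dose
dvh_query_V(curve, 0.30)  # 1.000: all of the lesion gets >= 30% dose
```

`run_pipeline(run_config(), "out/")` runs simulate → statistics →
coverage → DVH end to end and writes tidy CSVs plus a JSON manifest from
which every output is exactly reproducible.  A thin command-line wrapper
with `simulate`/`stats`/`coverage`/`dvh`/`run` subcommands is installed at
`inst/cli/iplmotion.R`.

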