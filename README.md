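# punctaprox

Proximity statistics for fluorescent puncta at organelle contact sites.

Many membrane proteins involved in inter-organelle communication appear in
fluorescence microscopy as diffraction-limited puncta scattered through the
cytoplasm. Deciding whether those puncta genuinely sit on an organelle — an
ER tubule, a mitochondrion, an ER–mitochondria contact site — or merely
overlap it by chance is non-trivial, because a dense organelle network
covers a large fraction of the cytoplasm and a "random" punctum is often
close to it anyway. `punctaprox` implements the trajectory-randomization
analysis that settles this question in live-cell time-lapse data, together
with the companion quantifications used in contact-site studies: immunogold
cluster densities on fixed-area electron micrographs, cofractionation
profile correlations, and Manders colocalization coefficients.

## The core statistic

For each cell, tracked punctum trajectories yield one minimal-distance
sample per detection: the Euclidean distance d (nm) from the subpixel
centroid to the nearest organelle-positive pixel, 0 if the centroid falls
on the organelle mask. The observed per-cell association fraction is

    F_obs = #{ d <= tau } / #{ d },    tau = 100 nm by default.

The chance level is estimated by a trajectory-randomization null: every
trajectory is repositioned rigidly — uniform random translation plus
uniform random rotation about its centroid — by rejection sampling until
the whole trajectory lies inside the cytoplasm mask, preserving its shape
(and hence its temporal autocorrelation) exactly. Averaging the same
statistic over replicates gives F_rand per cell, and the association claim
is tested across n cells with a two-sided paired t-test on F_obs − F_rand
(df = n − 1). Supporting statistics include the binned probability density
and empirical CDF of the distance samples, Pearson correlations with exact
t-transform p-values (t = r·sqrt(n−2)/sqrt(1−r²), df = n − 2), immunogold
cluster density (clusters/µm², mean ± SEM over equal-area images) with an
inside-or-within-30 nm mitochondria-association rule, and Manders M1/M2.

Everything is exercised on synthetic data the package generates itself:
blob-shaped cells with a tubular ER web and elongated mitochondria,
organelle-associated or free puncta with per-frame motion, PSF rendering
with Poisson + Gaussian noise, immunogold point fields, and correlated
fraction profiles — all with known ground truth, so every estimator can be
validated against the generating parameters.

## Worked example

```r
library(punctaprox)

p    <- cell_params(seed = 11, p_assoc = 0.5, n_frames = 6, n_puncta = 30)
cell <- generate_cell_geometry(p)
ts   <- simulate_puncta_tracks(cell, p)
st   <- render_timelapse(cell, ts, p)

res <- analyze_stack(st, organelle = "er",
                     cfg = randomization_config(n_replicates = 20, seed = 5))
res$observed          # 0.683  fraction of samples within 100 nm of the ER
res$randomized_mean   # 0.525  chance level for the same trajectories
```

Half the puncta were seeded ER-associated, so the observed fraction (68%)
clearly exceeds the chance level (52%) set by how much of this cell's
cytoplasm lies near its dense ER web. Across a multi-cell experiment the
paired design makes the excess unambiguous:

```r
simulate_association_experiment(n_cells = 5,
  base_params = cell_params(seed = 100, n_frames = 6),
  cfg = randomization_config(n_replicates = 20, seed = 42))
#> <association_summary> n = 5 cells, threshold 100 nm
#>   observed   75.87% +/- 0.44% (SEM)
#>   randomized 45.79% +/- 0.81% (SEM)
#>   paired t = 45.685, df = 4, p = 1.37e-06

pearson_test_from_r(0.633, 12)
#> <correlation_result> r = 0.633, n = 12, t = 2.586, df = 10, p = 0.02715
```

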