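# spinsys

Peak list registration analysis and spin system grouping for protein NMR.

## The problem

Grouping the peaks of a single NMR peak list into spin systems is the first
step of protein resonance assignment, and it needs per-dimension match
tolerances that users rarely know. Worse, experimental peak lists contain
*multiple sources of positional variance*: most peaks scatter with a small
dimension-specific standard deviation, a subset scatters several times more.
Any single uniform tolerance either loses the noisy peaks or overlaps the
dense ones.

`spinsys` implements three cooperating pieces:

1. **Registration analysis** (`register()`) -- finds the best mapping of an
   "input" peak list onto a "root" peak list over their comparable
   dimensions. Candidate mappings (i, j) are scored by *robustness*: the sum
   over their support set SS(i,j) -- the peak pairs (m, n) whose difference
   vectors agree with (i, j) within tolerance -- of Jaccard similarities
   between support sets, weighted by the upper-tail chi-square probability of

   chi2(i,j,m,n) = sum_l [ ((x_i[l]-x_m[l]) - (y_j[l]-y_n[l])) / (std[l]*2) ]^2,

   with df = number of comparable dimensions. The best mapping's support
   yields per-dimension offsets and standard deviations; the algorithm
   iterates until the standard deviations converge. *Pairwise* mode aligns
   two spectra; *self* mode registers a list against itself (offsets pinned
   to zero, identical mappings excluded) and recovers the within-list
   positional standard deviation per dimension -- the match tolerances,
   estimated from the data.

2. **Variance-informed grouping** (`group_peaks()`) -- DBSCAN over one peak
   list where the region query uses the variance-normalized distance
   sqrt(sum_k ((x_i[k]-x_j[k]) / sigma[k])^2) and the radius is the
   chi-square quantile sqrt(Qchisq_upper(p, df)) (default p = 1e-4,
   min_points = 2).

3. **The iterative pipeline** (`run_pipeline()`) -- self-register, group,
   collect the unclustered remainder, and repeat with the newly estimated
   (larger) variances: each tier peels off one variance population.

A peak-list simulator rounds the package out: `synth_assignments()` draws
assigned chemical-shift tables from typical per-residue-type priors,
`ideal_peaklist()` turns them into assigned peak lists through declarative
spectrum descriptions (HN(CO)CACB, NCACX, NCOCX configs bundled),
`add_noise()` injects single- or two-source Gaussian positional noise, and
`score_grouping()` / `aggregate_curve()` measure identified / overlapped /
split / missing spin systems against the simulated truth.

## A worked example

```r
library(spinsys)

table <- synth_assignments(80, seed = 1, protein_id = "demo")
pl <- simulate_peaklist(table,
                        noise = noise_model(c(0.004, 0.04, 0.04),
                                            fraction_high = 0.2,
                                            multiplier = 5),
                        seed = 2)

register(pl)
#> Registration analysis (self mode)
#>   64 mapped pairs, 4 iteration(s), converged
#>   dim H: offset +0.00000 ppm, std 0.01056 ppm (sigma 0.00747)
#>   dim N: offset +0.00000 ppm, std 0.10391 ppm (sigma 0.07347)

res <- run_pipeline(pl)
res
#> Registration + grouping pipeline: 3 tier(s), 69 cluster(s), 1 unclustered of 142 peaks
#>   tier 1: stds 0.00593/0.0584 ppm, 49 cluster(s)
#>   tier 2: stds 0.0289/0.338 ppm, 17 cluster(s)
#>   tier 3: stds 0.292/1.15 ppm, 3 cluster(s)

glance(score_grouping(res, sequence = sequence_of(table)))
#> # A tibble: 1 x 13
#>   observed_peaks ungrouped_peaks true_spin_systems groupable_spin_systems
#> 1            142               1                73                     69
#>   identified overlapped split partial missing pct_grouped ...
#> 1         65          7     0       0       1        91.5
```

Plain `register()` uses the classical standard deviation, so the 80/20
mixture inflates its estimate (sigma_H 0.0075 vs the 0.004 ppm base). The
pipeline instead registers each tier with a robust (MAD-based) scale: its
first tier locks onto the base population (std 0.0059 ppm, i.e. sigma
0.0042) and groups 49 low-variance systems; the second tier re-registers
the leftover peaks, finds the roughly five-fold larger scale of the
high-variance population (0.0289 ppm), and recovers 17 more. In the
evaluation, `identified` counts clusters that exactly match a true spin
system; percentages are reported both over all truth-labeled peaks (91.5%
here) and over *groupable* peaks, i.e. systems with >= min_points peaks
(94.2% -- the single CA peak following a glycine can never form a 2-peak
cluster).

A thin CLI wraps the same functions:

```sh
exec/peaktools simulate --n-proteins 5 --source two_all --steps 5 --outdir sims/
exec/peaktools pipeline --input sims/synt001_step01.json --format json --out result.json
exec/peaktools evaluate --result result.json --input sims/synt001_step01.json --out report.json
```

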