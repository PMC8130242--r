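# phantomdose

Effective dose estimation from point dosimetry in anthropomorphic phantoms.

`phantomdose` turns per-dosimeter absorbed doses — e.g. MOSFET readings
taken in a layered RANDO-style arm phantom — into ICRP 103 equivalent and
effective doses, and the comparison metrics radiology physicists report
when ranking imaging protocols: dose ratios against a radiography baseline,
mAs-normalised doses, modality group differences expressed as days of
natural background, and a propagated type A / type B uncertainty budget.
It is written for medical physicists and dosimetry researchers comparing
radiography, MSCT and CBCT protocols for extremity imaging, but the engine
is generic over any tissue map.

## The model

For a partially irradiated tissue *T* sampled at sub-structures *i*:

```
H_T = w_R * Σ_i f_i * D̄_{T,i}          (equivalent dose, w_R = 1 Sv/Gy for photons)
E   = Σ_T w_T * H_T                     (effective dose, ICRP 103 weights)
```

where `f_i` is the fraction of the tissue's whole-body mass inside the
exposed volume, `D̄_{T,i}` the mean absorbed dose of the dosimeters assigned
to sub-structure *i*, and remainder organs (muscle, lymphatic nodes) share
the collective remainder weight `0.12 / 13`. The package also estimates the
`f_i` themselves from phantom geometry and reference anatomy (bone
cross-sections for red marrow, surface-to-volume ratios for bone surface,
layer perimeters over the Du Bois body surface area for skin, summed muscle
masses, a configured lymph constant), propagates uncertainties as weighted
sums of variances with a k = 2 expanded value, and generates synthetic
replicate readings (lognormal noise) for validation.

## Worked example

The package ships a complete study fixture: 11 dosimeters, 7 protocols
across a radiography device (AP+LAT summed), an MSCT scanner and two CBCT
scanners.

```r
library(phantomdose)
library(dplyr)

res <- effective_dose(elbow_readings(), elbow_tissue_map(), elbow_protocols())
glance(res) |>
  select(protocol_id, effective_dose_uSv, mean_absorbed_mGy,
         normalized_uSv_per_mAs)
#> # A tibble: 7 × 4
#>   protocol_id        effective_dose_uSv mean_absorbed_mGy normalized_uSv_per_mAs
#>   <chr>                           <dbl>             <dbl>                  <dbl>
#> 1 newtom5g_hires_12…               6.11             2.19                   0.221
#> 2 newtom5g_std_12x8                1.86             0.664                  0.532
#> 3 newtom5g_std_15x12               2.40             0.945                  0.924
#> 4 newtom5g_std_18x16               2.01             0.827                  0.836
#> 5 planmed_verity                   2.43             1.06                   0.108
#> 6 shimadzu_fh21                    1.46             0.591                  0.116
#> 7 siemens_sensation               36.6             16.1                    0.318
```

Reading: the MSCT protocol deposits an effective dose of 36.6 µSv — about
25× the radiographic examination (1.46 µSv) — while the CBCT protocols stay
within 1.9–6.1 µSv. `tidy(res)` breaks each dose into per-organ
contributions (bone marrow carries ~50% throughout); `autoplot(res)` draws
the stacked composition.

The one-call pipeline adds ratios, correlation, group differences and the
uncertainty budget:

```r
fx <- paper_fixture()
report <- run_pipeline(fx$readings, fx$tissue_map, fx$protocols)
report$correlation
#> [1] 0.9995633
report$group_difference
#> # A tibble: 1 × 4
#>   mean_a_uSv mean_b_uSv difference_uSv background_days
#>        <dbl>      <dbl>          <dbl>           <dbl>
#> 1       36.6       2.96           33.6            3.96
```

The MSCT-minus-mean-CBCT difference of 33.6 µSv corresponds to about 4 days
of natural background radiation (3.1 mSv/yr); effective-dose ratios and
mean-absorbed-dose ratios rank the protocols near-identically
(r ≈ 0.9996).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/dosepipe.R compute \
  --readings inst/extdata/elbow_readings.csv \
  --tissue-map inst/extdata/icrp103_elbow.yaml \
  --protocols inst/extdata/protocols_paper.json \
  --out report/
```

See the vignette (`vignettes/effective-dose-methodology.Rmd`) for the model
assumptions, the fraction estimators, the uncertainty aggregation scheme
and the generator's noise model.

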