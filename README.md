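# dendromix

Dendroecological analysis of tree growth, species mixture, climate, and
insect epidemics in boreal stands of eastern Canada.

Black spruce (*Picea mariana*) and trembling aspen (*Populus
tremuloides*) co-occur in pure and mixed stands, and each hosts its own
defoliator — the spruce budworm (SBW) on spruce, the forest tent
caterpillar (FTC) on aspen. `dendromix` asks, from tree-ring data, whether
stand mixture changes a species' average growth, its long-term trend, its
climate sensitivity, and its vulnerability to (or release by) insect
outbreaks. It is aimed at dendroecologists working with basal-area
increment (BAI) chronologies.

## What it computes

For each of five chronology groups *y* (spruce in PBS/M/PTA stands, aspen
in PTA/M) the package builds the mean BAI chronology from per-tree ring
widths (distance-to-pith estimation, BAI conversion, 15-year minimum
cambial age, per-year mean with SEM) and fits

```
BAI_t,y = α_Baseline,y + Trend_t·α_Tr,y + SeasonLength_t·α_SL,y
        + SummerHeat_t·α_SH,y + Budworm_t·α_SB,y + Caterpillar_t·α_TC,y
        + ε_t,     ε_t ~ N(0, σ_y)
```

by component-wise random-walk Metropolis–Hastings (uniform priors on each
α, Jeffreys prior on σ; 60,000 iterations, first 10,000 discarded).
`Trend` runs −27 (1950) to +28 (2005); `SeasonLength` and `SummerHeat`
are April+September and June–August mean temperature anomalies; `Budworm`
is a 9-year triangular pulse centered on 1974; `Caterpillar` is 1 in
1980/2001 and 0.5 in 2000. Parameters are compared across chronologies
with the overlapping coefficient of their posteriors: overlap < 10% is a
significant difference. Supporting stages compute crossdating statistics
(mean sensitivity, first-order autocorrelation, leave-one-out series
intercorrelation), bootstrapped Pearson correlation functions against
monthly climate (95% percentile CIs, 1,000 resamples), and rankings of
year-over-year BAI changes against the epidemic calendar.

A synthetic-data generator (`synthetic_truth()`, `generate_study()`)
emulates the study population — 61/73/30/22/11 trees per group, group
baselines 2.5/3.0/2.2/9.3/8.8 cm², boreal western-Quebec monthly climate
— with known ground truth, so the whole pipeline is testable without
field data.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate.R` … `06_overlap_table.R`), writing
tables under `results/`. Equivalently, in R:

```r
library(dendromix)
cfg <- pipeline_config(out_dir = "results_demo", seed = 1L)
res <- run_all(cfg)
summary(res$fits$spruce_M)
```

The mixed-stand spruce fit prints (R² = 78%, acceptance 0.31):

```
           parameter    mean  median      sd  cri_lo   cri_hi
      alpha_baseline  2.8711  2.8711 0.04245  2.7879  2.95478
         alpha_trend -0.0192 -0.0192 0.00252 -0.0241 -0.01423
 alpha_season_length  0.2528  0.2524 0.03686  0.1804  0.32637
   alpha_summer_heat -0.1074 -0.1075 0.05064 -0.2065 -0.00874
           alpha_sbw -0.3574 -0.3556 0.16967 -0.6949 -0.02972
           alpha_ftc  1.0750  1.0754 0.20554  0.6681  1.47811
               sigma  0.2862  0.2833 0.02955  0.2357  0.35184
```

Read: mixed-stand spruce averages ~2.87 cm²/yr (generating truth 3.0),
grows more in years with warm April/September (α_SL > 0), loses growth
under summer heat and SBW defoliation (α_SH, α_SB < 0), and gains ~1 cm²
in FTC years when the aspen canopy opens (α_TC > 0) — the host/non-host
pattern the generator encodes. `res$overlaps` and `res$mixture_effects`
then reduce the five fits to the overlap-significant contrasts, e.g.
spruce baseline PBS vs M: direction `Lower`, overlap 0.000, significant.

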