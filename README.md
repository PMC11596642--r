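# pigmentax

Pigment-based chemotaxonomy for lake phytoplankton communities.

HPLC pigment tables are the cheapest wide-coverage window into who is
growing in a lake: each algal group carries a characteristic set of
accessory pigments (fucoxanthin for diatoms, peridinin for
dinoflagellates, alloxanthin for cryptophytes, zeaxanthin and echinenone
for cyanobacteria, chlorophyll *b* for green algae). `pigmentax` turns a
station × pigment concentration table into quantitative community
structure, for limnologists and bio-optical researchers who need
phytoplankton composition — cyanobacteria especially — without counting
cells under a microscope.

## What it computes

* **Dataset QA (Aiken criteria).** Total accessory pigments must co-vary
  with total chlorophyll *a*: ordinary least squares of log10(TAcc) on
  log10(TChl *a*) with the conventional acceptance rules (r² > 0.9, slope
  in 0.7–1.4, |TChl *a* − TAcc| < 0.3 TPig at ≥ 85% of stations).
* **CHEMTAX-style biomass estimation.** Given pigment concentrations S
  (stations × pigments) and an initial group × pigment ratio matrix F0,
  the solver minimises

  ‖ W ∘ (S − C·F) ‖_F

  over station-group biomasses C ≥ 0 (as mg TChl *a*/m³) and ratios F
  confined to an element-wise box around F0 (default ratio limit ±500%,
  structural zeros fixed, TChl *a* column ≡ 1), by alternating exact
  non-negative / box-constrained least squares. The weighted RMSE trace is
  non-increasing by construction.
* **Size structure.** Diagnostic-pigment proportion factors
  mPF = (Fuco+Peri)/D, nPF = (Hex+But+Allo)/D, pPF = (Zea+TChl *b*)/D with
  D the total diagnostic pool, plus ternary plot coordinates.
* **Multivariate structure.** PCA of pigment:TChl *a* ratios via SVD
  (X = UΣVᵀ, variance fractions from the singular values), and
  hierarchical clustering of pigments with Ward linkage on Pearson
  correlation distance d = 1 − r, cut at linkage distance 0.5; stations
  are then assigned to the best-correlated pigment cluster.
* **Pigment networks.** Similarity s_ij = |corr(x_i, x_j)|,
  soft-thresholded adjacency a_ij = s_ij^β (β = 6), Louvain community
  detection with weighted modularity Q (Q > 0.3 read as strong
  structure), and station maps of the dominant pigment community.
* **Seasonal statistics.** One-way ANOVA per variable across seasons with
  Tukey–Kramer pairwise comparisons.
* **Synthetic data.** A calibrated generator (27 stations, 5 campaigns,
  3 seasons; lognormal group biomasses summing to the surveyed total
  chlorophyll *a* marginal of 2.933 mg/m³ at CV ≈ 55%; pigments via a
  known ratio matrix; LOD censoring; multiplicative noise) with hidden
  ground truth for end-to-end parameter-recovery testing.

## Worked example

```r
library(pigmentax)

syn <- generate_pigment_data(generator_config(seed = 42))
m <- syn$matrix
m
#> <pigment_matrix> 27 stations x 26 pigments [mg/m3]
#>   below-LOD cells: 180

aiken_verdict(derive_sums(m))
#> <qa_report>
#>   log10(TAcc) ~ log10(TChl a): slope 0.833, r2 0.847
#>   stations passing |TChl a - TAcc| < 0.30 TPig: 0%
#>   dataset pass: FALSE

fit <- fit_chemtax(m, example_f0(seed = 1))
fit
#> <chemtax_result> 27 stations x 6 groups; rmse 0.07302 after 500 iterations (converged: FALSE)
round(head(fit$C, 3), 3)
#>      Diatoms Chlorophyceae Cyanophytes Chrysophytes Dinophyceae Cryptophytes
#> m1s1   0.429         0.384       0.621        0.877       0.128        1.133
#> m1s2   1.216         0.422       0.572        0.774       0.386        0.713
#> m1s3   0.653         0.574       0.849        0.735       0.203        0.884

r <- ratios_to_tchla(m)
detect_communities(build_network(r[, apply(r, 2, sd) > 0]), seed = 42)
#> <network_communities> 4 communities, Q = 0.509 (strong structure)
```

Reading the output: the QA slope (0.833) sits inside the 0.7–1.4 band and
r² just misses 0.9, while the per-station relative-difference rule fails —
the generator inherits a real property of this kind of survey, where the
fitted ratio matrix accounts for only part of the accessory pigment pool
(see the vignette). `fit$C` is each station's biomass split across the six
groups in mg TChl *a*/m³ (here, station m1s1 is cryptophyte-leaning,
m1s2 diatom-leaning; `converged: FALSE` means the iteration cap — the
deliberate regularizer — stopped the refinement, not a failure). The
pigment network splits into four communities with strong structure
(Q = 0.509 > 0.3): the three built-in size-class blocks plus the
degradation/rare pigments.

A station CSV produced by the generator, the refined lake ratio matrix,
an example F0 and an example pipeline config ship under `inst/extdata/`
(the station table is synthetic, as its filename says).

## Command line

```sh
Rscript inst/cli/pigmentax.R generate --out out/ --seed 1
Rscript inst/cli/pigmentax.R qa --input out/stations.csv --out out/
Rscript inst/cli/pigmentax.R chemtax --input out/stations.csv \
    --f0 inst/extdata/example_f0.csv --ratio-limit 500 --out out/
Rscript inst/cli/pigmentax.R run --config inst/extdata/example_config.yaml --out out/
```

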