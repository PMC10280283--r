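# phca — persistent-homology classification of point clouds

`phca` is an R package for supervised classification of points in Euclidean
space by topological disturbance. Each class of a labeled feature table is
treated as a point cloud; a query point is assigned to the class whose
persistent homology changes least when the query is added. The package is
aimed at analysts who want a geometry-aware classifier for moderate-sized
numeric datasets (morphometric measurements, sampled surfaces, engineered
feature vectors) and at anyone who needs the underlying topological
machinery — Vietoris–Rips filtrations, persistence diagrams, bottleneck and
Wasserstein distances — in plain, dependency-light R.

## The classifier

For each class *i*, let *X<sub>i</sub>* be its training cloud and
*P(X<sub>i</sub>)* its persistence diagram: the multiset of (dimension,
birth, death) features of the Vietoris–Rips filtration of *X<sub>i</sub>*,
grown up to a maximum scale *maxsc* and capped there. Given a query point α,
set *Y<sub>i</sub> = X<sub>i</sub> ∪ {α}* and score

> Score(X<sub>i</sub>) = | Σ<sub>a ∈ P(Y<sub>i</sub>)</sub> life(a) −
> Σ<sub>b ∈ P(X<sub>i</sub>)</sub> life(b) |,

the absolute change in **total persistence** (the sum of feature lifespans
death − birth). The query is classified to arg min<sub>i</sub>
Score(X<sub>i</sub>): the class least disturbed topologically. If the query
duplicates a training point of class *p*, Score(X<sub>p</sub>) = 0 exactly.

With the default `maxdim = 0` only connected-component features are used,
and the package exploits the identity *total finite H₀ persistence = ½ ×
minimum-spanning-tree weight* (radius convention): fitting stores each
class's spanning forest, and scoring a query is a single Kruskal pass over
the stored forest plus the query's star of edges. Higher homology dimensions
(`maxdim ≥ 1`) run the full boundary-matrix reduction over F₂.

Also included:

* exact bottleneck and q-Wasserstein distances between diagrams,
* stratified k-fold cross-validation, confusion matrices and per-class
  precision / recall / specificity / F1 reports,
* the Nemenyi post-hoc comparison across classifiers,
* benchmark adapters for LDA, CART, KNN, SVM and random forests,
* a generator for the three-surface synthetic benchmark (circle
  x² + y² = 25, unit sphere centred at z = 1, torus of ring radius 3 and
  tube radius 1 centred at z = −1; 200 points uniform on each).

## Worked example

```r
library(phca)

syn <- generate_synthetic(n_per_surface = 200, seed = 1)
fit <- phca(syn, label = "label")
tidy(fit)
#> # A tibble: 3 × 5
#>   class  n_points n_features maxscale reference_total
#>   <chr>     <int>      <int>    <dbl>           <dbl>
#> 1 circle      200        200     5.00            20.3
#> 2 sphere      200        200     5.00            21.3
#> 3 torus       200        200     5.00            52.7
```

The global `maxscale` resolves to 5: half the largest pairwise distance in
the pooled training set (the circle's diameter, 10). Each class contributes
200 dimension-0 features; `reference_total` is the capped total persistence
of the class diagram. A point near the circle scores lowest there:

```r
phca_score(fit, data.frame(x = 4.9, y = 0.3, z = 0.05))
#> # A tibble: 1 × 4
#>   score_circle score_sphere score_torus .pred_class
#>          <dbl>        <dbl>       <dbl> <fct>
#> 1       0.0236         2.01       0.614 circle
```

Inserting the point into the circle cloud barely reroutes its spanning
tree (score 0.024), while gluing it onto the sphere would cost about 2 units
of new tree length. Cross-validated comparison against standard baselines:

```r
bench <- run_benchmark(syn, methods = c("phca", "lda", "knn"),
                       k_folds = 5, seed = 1)
glance(bench)
#> # A tibble: 3 × 3
#>   method accuracy     n
#>   <chr>     <dbl> <dbl>
#> 1 phca      1       600
#> 2 lda       0.818   600
#> 3 knn       0.998   600
```

PHCA separates the three surfaces perfectly; LDA cannot, because the class
means differ essentially only along z, so its linear rule misroutes the
lower hemisphere of the sphere and the upper half of the torus tube.
`tidy(bench$nemenyi)` reports the pairwise mean-rank comparisons.

A command-line wrapper with `synth`, `fit`, `predict` and `evaluate`
subcommands is installed under `inst/cli/phca.R`:

```sh
Rscript inst/cli/phca.R synth --n 200 --seed 1 --out synthetic.csv
Rscript inst/cli/phca.R fit --data synthetic.csv --out model.json
Rscript inst/cli/phca.R predict --model model.json --data queries.csv --out pred.csv
```

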