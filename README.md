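# OrthoSDP

Sequence–function mapping across orthologous receptor proteins.

Closely related species often carry orthologs of the same olfactory
receptor whose odorant response profiles (spike counts from
single-sensillum recordings) have diverged. OrthoSDP is for researchers who
have (a) a protein multiple sequence alignment of such orthologs, (b) a
matched receptor × odorant response matrix, and optionally (c) a 3D model
of the reference receptor, and who want to know *which amino-acid positions
determine the response*, *how well the response of an unseen species can be
predicted from sequence alone*, and *whether the determinant positions
cluster in functionally meaningful regions of the structure*.

## The method

**Position ranking.** For alignment column *c*, receptor pairs are split by
whether they match at *c*; the column's score is

    s(c) = mean D(i,j) over mismatched pairs − mean D(i,j) over matched pairs

where D(i,j) is the mean absolute response difference (spikes) over the
odorants measured in both receptors. The top K eligible columns (K = 20 by
default) are the response-determining positions.

**Leave-one-out prediction.** Each receptor is held out in turn; the
columns are re-ranked on the remaining receptors, and the held-out response
to each odorant is predicted as the similarity-weighted mean of the
training responses, with weights simᵅ taken from the fraction of identical
residues at the top-K positions (α = 1 by default). The prediction error
D_Pred,Actual is compared against D_Ctrl,Actual, the error of the same
predictor after permuting the assignment of training response rows to
training sequences (exact enumeration when the permutation count fits the
shuffle budget, seeded Monte-Carlo otherwise).

**Jackknife robustness.** The top-K set is recalculated once per excluded
species; the package reports how often each position recurs and how many of
the original top-K are retained per exclusion.

**Structural enrichment.** All residues within 15 Å (Cα–Cα, boundary
inclusive) of a seed residue form a neighborhood of size n; the overlap k
between the neighborhood and the top-K set in a protein of length N has
expectation nK/N, and P(X ≥ k) is computed by exact log-space hypergeometric
summation. A parameters-only mode reproduces printed tests from (N, K, n, k)
without a structure file.

A seeded synthetic-data generator (`generatorConfig()` /
`generateDataset()`) produces alignment + responses + structure with
planted determinant positions and known noise, for calibration and
end-to-end benchmarking.

## Worked example

```r
library(OrthoSDP)

ds  <- generateDataset(generatorConfig(seed = 1))   # 14 receptors, 397 aa, 21 odorants
pst <- rankPositions(ds@alignment, ds@responses, k = 20)

ds@truth$plantedPositions
#> [1]  46  68 281 311 370
intersect(topPositions(pst), ds@truth$plantedPositions)
#> [1]  68  46 370 311 281

jackknifeTopPositions(ds@alignment, ds@responses, k = 20)
#> JackknifeResult: k = 20 , 14 exclusions
#>   mean retention = 18.29 / 20
#>   frequency-top matches original: 20 / 20

hypergeomEnrichment(N = 397, K = 20, n = 41, k = 6)
#> NeighborhoodEnrichment: seed none (union/parameters-only)
#>   overlap 6 of n = 41 (expected 2.07; N = 397, K = 20)
#>   P(X >= 6) = 0.0109
```

All five planted determinant positions are recovered within the top 20; the
jackknife retains on average 18.3 of the 20 positions per exclusion and the
20 most frequent positions across recalculations coincide with the original
set; the enrichment example shows a 41-residue neighborhood holding 6 top
positions where 2.07 are expected by chance (p = 0.011).

A command-line wrapper over the same functions is provided at
`inst/scripts/orthosdp.R` with subcommands
`simulate | rank | loo | robustness | enrich | all`.

## Documentation

The methods vignette
(`vignettes/response-determining-positions.Rmd`) describes the model and
its assumptions, the tunable parameters, what the synthetic generator does
and does not emulate, and the numerical conventions; function-level
documentation is in the roxygen comments under `R/`.
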