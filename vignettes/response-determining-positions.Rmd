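---
title: "Mapping response-determining positions across receptor orthologs"
author: "OrthoSDP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping response-determining positions across receptor orthologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrthoSDP)
```

## The problem

Orthologous olfactory receptors — the same receptor gene carried by closely
related species — often differ at only a modest number of amino-acid
positions, yet their odorant response profiles (spike counts from
single-sensillum recordings) can diverge substantially. OrthoSDP asks three
questions about such a panel:

1. **Which alignment columns determine the response?** For every column of
   the ortholog alignment, receptor pairs are split into those that *match*
   (identical residue) and those that *mismatch* at the column, and the
   column's score is

   $$s(c) \;=\; \overline{D}_{\text{mismatch}}(c) \;-\;
                \overline{D}_{\text{match}}(c),$$

   where $D(i,j)$ is the mean absolute response difference (in spikes) of
   receptors $i$ and $j$ over the odorants both were measured on. A large
   positive $s(c)$ means residue identity at $c$ predicts response
   similarity. The top $K$ eligible columns (default $K = 20$) form the
   response-determining set.

2. **Can the response of an unseen species be predicted?** Leave one
   receptor out, re-rank the columns on the remainder, and predict each
   held-out response as the similarity-weighted mean of the training
   responses, with weights $w_j = \mathrm{sim}(h, j)^\alpha$ where
   $\mathrm{sim}$ is the fraction of identical residues at the top-$K$
   positions (gap-free columns only) and $\alpha = 1$ by default. The
   prediction error $D_{\text{Pred}} = |\hat r - r|$ is compared to
   $D_{\text{Ctrl}}$, the mean error of the same predictor after permuting
   the assignment of training response rows to training sequences.

3. **Do the top positions cluster in the 3D structure?** Given alpha-carbon
   coordinates of the reference receptor, all residues within a fixed radius
   (default 15 Å, boundary inclusive) of a seed residue form a neighborhood;
   the overlap between the neighborhood (size $n$) and the top-$K$ set in a
   protein of length $N$ has expectation $nK/N$ under random placement, and
   the exact upper-tail hypergeometric probability $P(X \ge k)$ quantifies
   over-representation. The canonical application uses seeds R166 (pore
   entrance) and F265 (putative binding pocket) on a 397-residue receptor.

## A worked example on synthetic data

```{r example}
ds <- generateDataset(generatorConfig(seed = 1))
pst <- rankPositions(ds@alignment, ds@responses, k = 20)
intersect(topPositions(pst), ds@truth$plantedPositions)

jk <- jackknifeTopPositions(ds@alignment, ds@responses, k = 20)
jk

hypergeomEnrichment(N = 397, K = 20, n = 41, k = 6)
```

## Design decisions and their rationale

**Score definition.** The mismatch-minus-match form is monotone in "residue
identity predicts response similarity", is expressed in spikes, and is
recoverable by brute-force pair enumeration, which the test suite uses as an
independent oracle on small instances. Pairs with a gap (or the unknown
residue `X`) at the column are excluded from both sets; a column is eligible
only if both sets are populated (configurable minimum, default 1 pair).
Ties are broken by smaller reference residue index, then smaller column, so
output is deterministic.

**Distance metric.** Mean absolute difference over shared odorants matches
the absolute-error scale of $D_{\text{Pred}}$/$D_{\text{Ctrl}}$ and is
robust to missing entries: a receptor pair contributes whatever odorants
both were measured on, and pairs sharing none are dropped from column
scoring.

**Shuffled control.** The control permutes training response *rows* against
fixed sequences. This preserves the response distribution and the
predictor's functional form while destroying the sequence–response linkage.
When the number of training receptors is small enough that all permutations
fit in the shuffle budget, the control enumerates them exactly — the
Monte-Carlo estimate and the exhaustive average then coincide by
construction, which the tests assert against an independent enumeration.
Each held-out receptor gets its own stream, derived deterministically from
the master seed and the receptor's alphabetical rank, so reports are
invariant to storage order.

**Weight exponent.** $\alpha = 1$ (linear similarity) is the minimal
choice and the default. Because ortholog similarities at 20 positions vary
over a narrow band, linear weights concentrate only weakly on the most
similar training receptors; raising $\alpha$ sharpens the predictor toward
nearest-neighbor behavior. The exponent is exposed rather than tuned: the
similarity is an unweighted fraction over the top-$K$ columns, so when only
a subset of those columns carries real signal, the uninformative columns
dilute the similarity regardless of $\alpha$ — a structural property of the
similarity definition worth keeping in mind when interpreting improvement
percentages on data where $K$ exceeds the number of true determinants.

**Improvement, two ways.** The overall improvement
$100\,(\overline{D}_{\text{Ctrl}} - \overline{D}_{\text{Pred}}) /
\overline{D}_{\text{Ctrl}}$ and the mean of per-receptor improvements
generally differ; `PredictionReport` reports both, labeled
`improvementPercent` and `meanPerReceptorImprovement`.

**Jackknife.** Removing one species at a time, the top-$K$ set is
recalculated; robustness is summarized as (i) the frequency with which each
column appears across recalculations and (ii) the per-exclusion retention of
the original top set. Retention measures ranking *stability*, not signal:
each reduced dataset shares most receptor pairs with the full one, so even
signal-free rankings are substantially retained. The suite therefore asserts
the monotone property — retention does not improve as response noise grows —
rather than treating low retention as a null signature. Frequency ties
straddling rank $K$ are broken by the full-dataset score, then reference
index.

**Enrichment conventions.** The seed residue belongs to its own neighborhood
(distance 0), distances are between alpha-carbons (the conventional residue
proxy; the choice of atom is not material at a 15 Å radius), a boundary
distance of exactly the radius is inside, and the test is one-tailed
(upper), since the question is over-representation. The p-value is computed
by log-space summation of the hypergeometric tail and cross-checked in the
tests against both `stats::phyper` and exact `choose()` enumeration.
A parameters-only mode (`hypergeomEnrichment`) reproduces printed tests
from $(N, K, n, k)$ alone, with no structure file.

**Percent identity.** The denominator is the number of columns where at
least one of the pair is non-gap; columns gapped in both are excluded. This
matches the "pairwise identity" of common alignment viewers. Whether
published identity heatmaps used this or an ungapped-overlap denominator is
not always stated; the choice is exposed in the documentation rather than
configurable.

## What the synthetic generator emulates — and what it does not

`generatorConfig()` defaults describe a 14-receptor ortholog panel with a
397-residue reference, 21 odorants, and responses centered at 28.78 spikes —
the scale of a single-sensillum recording screen. Five planted determinant
positions carry additive, position-specific residue effects with SD
$\tau = 30$ spikes; 40 further columns vary without affecting responses;
measurement noise has SD $\sigma = 5$ spikes. Each variable column uses a
two-letter alphabet (ancestral plus one alternative, carried with
probability 0.3 per receptor), which keeps match/mismatch pair counts
well-populated at 14 receptors, and substitution draws are repeated until
each designated column is variable by construction.

The generator deliberately omits phylogenetic correlation (a star phylogeny,
not a species tree), epistasis between positions, odorant-panel structure,
and realistic indel processes (at most one designated gap column). Passing
the recovery and calibration tests therefore shows the machinery is correct
and the statistic consistent under the generative model — not that real
ortholog panels satisfy that model. In particular, with a star phylogeny and
only 14 receptors, background columns whose random carrier patterns collide
with a planted column's pattern score identically to it, so exact top-rank
recovery is only guaranteed when background variation is absent; with the
default 40 background columns the suite asserts median recovery of at least
4 of 5 planted positions within the top 20 under noise, which is the
realistic regime.

The zero-noise "strong signal" configuration used for the jackknife
machinery check sets `nVariableBackground = 0`, `substitutionProb = 0.5`,
`noiseSd = 0` and $K = 5$ (the planted-set size): retention equal to $K$
under every exclusion is only a well-posed expectation when every member of
the top set is a true determinant, which fails by construction when
$K$ exceeds the number of planted positions.

## Numerical and degenerate-input conventions

All indices are 1-based; reference numbering is authoritative for reporting.
`X` matches nothing, including another `X`. Columns where the reference is
gapped are scored but reported with an undefined reference index and sort
after mapped columns at equal score. Predictions fall back to the unweighted
training mean when all weights are zero, and are missing when no training
receptor was measured on the odorant; missing entries are excluded from all
averages and counted in the report. Tabular outputs are written with fixed
6-significant-digit formatting and sorted keys so identical runs are
byte-identical; the response CSV writer keeps 12 significant digits so
generator fixtures round-trip losslessly at test tolerance.

Problem sizes in the test suite follow the panel scale above (14 x 397 x 21,
20 seeds for recovery, 10 seeds for end-to-end evaluation, controls with up
to 1000 permutations); the hypergeometric oracle sweep covers every
parameter combination with $N \le 25$.

## Known limitations

- Receptor pairs are treated as independent; shared phylogenetic history is
  not corrected for, so scores on real ortholog panels overstate effective
  sample size.
- The predictor is a convex combination of training rows: it cannot predict
  responses outside the observed training range.
- The hypergeometric test conditions on the neighborhood size $n$; it does
  not model spatial autocorrelation of the top positions along the chain.
- Published neighborhood sizes depend on the structure model used to define
  them; reproducing a printed $n$ exactly requires the same coordinates,
  whereas the p-value from printed $(N, K, n, k)$ is reproducible without
  them.
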