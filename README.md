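# operand

Early-warning analysis for scalar time series: does the *dimensionality*
of a signal rise just before a transition?

Behavioural and biomedical signals (mood ratings, sentiment scores,
physiological traces) are shaped by a context that is hard to model
directly. One way to quantify that context is the number of degrees of
freedom the signal needs: if the dynamics generating the signal become
higher-dimensional shortly before an abrupt change, the embedding
dimension required to reconstruct the dynamics should rise in the
windows immediately preceding the change. `operand` implements this
indicator end to end:

1. **Onset detection** — a transition onset is any time `t` where the
   absolute first difference `|x_t − x_{t−1}|` exceeds a threshold θ.
2. **Window bookkeeping** — set **A** holds the length-`w` windows
   ending exactly at each onset; set **B** (reference) tiles everything
   at least `w` away from any onset, sliding with step 20.
3. **Optimal embedding dimension** (per window) — false nearest
   neighbours: a nearest neighbour at dimension `m` is *false* if
   extending to `m + 1` either stretches the pair by more than a factor
   `r_tol` or beyond `a_tol` times the attractor size. The optimal `m*`
   is the smallest `m` whose false-neighbour fraction drops below 1 %.
4. **Transitivity dimension** (per window) — the recurrence matrix
   `R_ij = 1 ⟺ ‖x̂_i − x̂_j‖ ≤ ε` is read as the adjacency matrix of a
   recurrence network; with the global transitivity
   `T = (closed length-2 paths) / (all length-2 paths)`, the dimension
   estimate is `D_T = log T / log(3/4)` (exactly `m` for uniform
   `m`-dimensional sets under the maximum norm).
5. **Comparison** — medians of each measure over sets A and B, with
   two-sided Wilcoxon rank-sum p-values (exact permutation enumeration
   for small samples, midranks under ties).

The package also ships the text front end used to turn raw text into an
emotional-polarity series (POS filtering, lemmatisation, semantic
orientation of each word against positive/negative paradigm word sets
via co-occurrence cosines), and seeded synthetic generators (Lorenz,
Henon, sine, AR(1), planted-step series, toy corpora) so that every
stage is testable without external corpora.

## Worked example

```r
library(operand)

b <- make_dimension_shift_series(benchmark_spec(seed = 1))
report <- operand_analyze(b$series, theta = 5)
print(report)
#> Pre-onset vs reference dimensionality report
#>   onsets: 10 (theta = 5), windows: 10 pre-onset / 45 reference
#>   embedding dimension m*:      median A = 3.5, median B = 1, p = 3.04e-13
#>   D_T (fixed embedding):       median A = 1.46, median B = 1.73, p = 1.09e-05
#>   D_T (dynamic embedding):     median A = 1.35, median B = 0.608, p = 5.5e-07
#>   direction flags: m_up = TRUE, dt_fixed_down = TRUE, dt_dynamic_up = TRUE
```

The benchmark plants ten onsets; the 100 points before each onset come
from a chaotic (Lorenz) source while the reference stretches are a
sine. The report shows the three signatures the indicator is built
around: the optimal embedding dimension is *higher* before onsets
(median 3.5 vs 1), the transitivity dimension under a *fixed* embedding
is paradoxically *lower* before onsets (1.46 vs 1.73) — the fixed
embedding distorts windows whose dynamics it does not fit — and under
*dynamic* (per-window optimal) embedding the transitivity dimension
moves in the same direction as the embedding dimension again (1.35 vs
0.61).

The text front end:

```r
demo <- make_demo_polarity_model()
s <- text_to_series(demo_sentences(), demo$paradigms, demo$model)
head(attr(s, "tokens")$lemma)
#> [1] "sunny"    "day"      "friendly" "child"    "travel"   "green"
round(head(as.numeric(s), 6), 3)
#> [1] 0.848 0.357 0.645 0.462 0.874 0.559
```

Each retained content word is scored by its semantic orientation —
cosine similarity to the summed context vectors of the positive
paradigm words minus that of the negative ones — yielding the polarity
series that `operand_analyze()` consumes.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "operand.R", package = "operand"))')" \
  analyze --input series.csv --theta 0.8 --out report.json
```

Subcommands: `analyze`, `text2series`, `synth step|dimshift|corpus`;
see `--help`-style usage by running it without arguments.

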