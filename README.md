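# premirnet

Discriminating true precursor microRNAs from length-similar pseudo hairpins
is a classic hard-negative problem in small-RNA genomics: both classes are
~60-130 nt, both fold into stem-loops, and composition alone barely
separates them. `premirnet` implements a feature-rich classification
pipeline for this task in idiomatic tidyverse R:

1. **Feature extraction** — a 591-dimensional named vector per hairpin:
   - 87 **profile features** (`psi.*`) from a position-specific scoring
     matrix (PSSM): scores are mapped through `s' = 2^(0.1 s)` and
     row-normalised into a frequency matrix `f`; the consensus sequence
     `CS(i) = argmax_j f_ij` (nucleotides only) yields its composition
     `NCCS(j) = n(j)/L`, the entropy `ECS = -Σ NCCS ln NCCS`, the mean
     row entropy `EFM = -(1/L) Σ_i Σ_j f_ij ln f_ij`, consensus 2-/3-mer
     frequencies, and GC content;
   - 24 **structure-graph descriptors** (`net.*`) of the nucleotide network
     (backbone + base-pair edges from a dot-bracket structure): degree,
     betweenness, coreness, constraint, hub score, transitivity, density,
     modularity, diameter, girth, motif counts, and friends;
   - 480 **Hilbert-Huang features** (`hht.*`): 15 dinucleotide
     physicochemical time series per sequence, each decomposed by empirical
     mode decomposition, with 4 Hilbert-spectral statistics for each of 8
     IMF slots.
2. **Feature selection** — greedy mRMR ranking
   (`max_f [I(f, class) − mean_g I(f, g)]` with 3-bin discretized mutual
   information) and incremental feature selection over ranked prefixes,
   scored by jackknife accuracy.
3. **Classification** — RBF-kernel SVM (LIBSVM via e1071) with per-fold
   z-score standardization, jackknife (leave-one-out) evaluation, grid
   search, and Sn / Sp / Acc / Mcc metrics.

A seeded synthetic benchmark (planted hairpins vs dinucleotide-shuffled
negatives with perturbed one-hot PSSMs) makes the whole pipeline runnable
and testable without external databases. PSSMs and RNAfold structures, when
you have them, are inputs — the package never runs an alignment search.

## Worked example

```r
library(premirnet)

corpus   <- synth_corpus(n_pos = 50, n_neg = 50, seed = 1)
features <- extract_features(corpus)
dim(features)
#> [1] 100 593          # id + label + 591 features

metrics <- svm_jackknife(features)
metrics[, c("sn", "sp", "acc", "mcc")]
#> # A tibble: 1 × 4
#>      sn    sp   acc   mcc
#>   <dbl> <dbl> <dbl> <dbl>
#> 1   0.9     1  0.95 0.905

ranking <- mrmr_rank(features)
head(ranking, 3)
#> # A tibble: 3 × 4
#>    rank feature        relevance objective
#>   <int> <chr>              <dbl>     <dbl>
#> 1     1 net.V_coreness    0.429     0.429
#> 2     2 net.A_Burts       0.334    -0.0626
#> 3     3 psi.tri_AAC       0.00846  -0.0855
```

The jackknife accuracy of 0.95 says the pipeline recovers the planted
structural signal; the top-ranked feature, the variance of graph coreness,
is a direct readout of the stem — shuffled negatives fold into scattered
short helices instead of one long stem. `ifs_select()` then finds the
smallest ranked prefix with maximal jackknife accuracy, and
`autoplot()` / `tidy()` / `glance()` work on its result.

A thin CLI over the same functions lives at `inst/cli/premirnet.R`
(`synth`, `extract`, `select`, `evaluate`, `run-all`).

## Documentation

The methods vignette (`vignettes/premirnet-methods.Rmd`) describes the
model: the profile, graph and Hilbert-Huang feature definitions, the
selection and evaluation protocol, every tunable with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical conventions.
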