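---
title: "Objective Q-methodology for built-environment orientation typing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective Q-methodology for built-environment orientation typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qorient)
```

## The problem and the method

Care institutions publish environmental imagery and text that signal which
aspects of their built environment they prioritize — indoor safety and
lighting, circulation and entrances, gardens and shade, or rehabilitation
equipment and open space. `qorient` types those latent orientations with Q
methodology, the inverted ("by-person") variant of factor analysis: instead
of factoring correlations between variables, it factors correlations between
whole *Q-sorts* — complete rankings of a fixed statement set — so each factor
is a shared viewpoint and each institution loads on the viewpoints it
resembles.

Classical Q methodology needs human participants to sort statements. Here
the sorting is *objective*: each institution is represented by the
L2-normalized mean embedding of its free-text environmental audit records,
each statement by its own embedding, and the institution's "agreement" with
a statement is their cosine similarity. Ranking those similarities and
forcing them into the fixed quasi-normal grid produces a Q-sort without any
human sorter. The statement set itself is data-constrained rather than
researcher-authored: audit sentences are embedded, reduced by PCA, clustered
by K-means, and each cluster contributes its centroid-nearest, sufficiently
discriminative sentences.

The pipeline, end to end:

1. **Corpus** — audit records per institution (`read_corpus()`, or
   `generate_corpus()` for synthetic data).
2. **Statement building** — `segment_sentences()` →
   `embed_texts()` → `reduce_dimensions()` → `select_k()`/`cluster_sentences()`
   → `extract_statements()` (wrapped by `build_statements()`).
3. **Q-sorting** — `build_qsorts()`: joint-batch embedding, per-institution
   aggregation, cosine scoring, `force_distribution()` into the grid.
4. **Inverted factor analysis** — `q_analyze()`: Pearson correlation of
   sorts, PCA extraction, Kaiser–Guttman screening, varimax (optionally
   manual) rotation, defining-sort flagging, weighted z-scores, factor
   arrays, composite reliability, distinguishing/consensus statements.

## Model details and conventions

**Embedding.** The default backend hashes lowercase tokens into 4096 buckets
(multiplicative hash modulo $2^{31}-1$, fixed hash seed 3491) and weights
counts by TF-IDF with $\mathrm{idf} = 1 + \log(N/\mathrm{df})$, computed over
the embedding batch and frozen once per run; statements and documents are
embedded in one joint batch so they share document statistics. Rows are
L2-normalized, so dot products are cosines. The backend is deterministic and
needs no model download; a sentence-transformer can be registered through
`register_embedding_backend()` when richer semantics are wanted. Similarity
is cosine throughout: bounded, scale-free, and the standard choice for
sentence embeddings. Scores are used only ordinally — the forced
distribution discards magnitudes — so any strictly increasing recalibration
of similarities leaves every Q-sort unchanged.

**Choosing K.** For each candidate K, K-means runs with k-means++ seeding,
10 restarts, convergence tolerance $10^{-6}$, and at most 300 Lloyd
iterations. The within-cluster sum of squares gives the elbow curve
(reported, not decisive); the decision combines the mean silhouette (rank
descending) and the Davies–Bouldin index (rank ascending) into a rank sum,
ties resolved toward the smaller K. PCA retains 90% of variance by default
before clustering; with a target of 1.0 the projection is an isometry, so
clustering reduced full-rank data reproduces clustering the raw data.

**Statement extraction.** Within each cluster, sentences are ranked by
distance to their own centroid; the discriminative margin is the distance to
the nearest other centroid minus the distance to the own centroid, and
sentences with margin $\le 0$ are excluded (a sentence no closer to its own
theme than to a neighboring one cannot represent it). Near-duplicates above
cosine 0.95 are dropped, keeping the closer-to-centroid sentence and
refilling from the ranking. Defaults of 18 clusters × 3 statements yield the
54-statement Q set the default grid expects.

**The grid.** Eleven levels from −5 to +5 with counts
(2, 3, 5, 6, 7, 8, 7, 6, 5, 3, 2): a symmetric quasi-normal allocation
summing to 54. Counts are configurable (`q_grid()`) and validated against
the statement count; symmetry guarantees every column has mean zero and a
common standard deviation, which is what makes by-person Pearson
correlations comparable. Ties in a score profile are broken by ascending
statement index — deterministic and bit-reproducible.

**Extraction and screening.** Factors are leading eigenpairs of the
by-person correlation matrix; loadings are eigenvectors scaled by
$\sqrt{\lambda}$, each column sign-flipped so its largest-magnitude loading
is positive (eigenvector signs are arbitrary; reports must be stable).
Explained variance per factor is $100\lambda/n$. The loading significance
threshold is $z_{crit}/\sqrt{m}$ for $m$ statements (0.351 for 54 statements
at $z=2.58$, i.e. P < 0.01). The admissible factor count requires an
eigenvalue strictly above 1.0 *and* at least two sorts that load
significantly and carry the strict majority of their communality on the
factor. The second clause matters: when sorts far outnumber statements the
correlation matrix is rank-deficient (rank at most $m-1$) and its residual
eigenvalues are inflated far above 1, so the bare eigenvalue rule admits
every factor; requiring two would-be defining sorts is what actually stops
the count at the scree inflection, mirroring how the eigenvalue rule, the
two-sort rule and the scree plot are applied jointly in Q practice. On
synthetic four-type corpora the planted factors carry dozens of
defining-style sorts and the residual factors none, so the screen is
decisive and deterministic.

**Rotation.** Varimax maximizes the Kaiser-normalized criterion by cyclic
pairwise planar rotations with the closed-form optimal angle; the criterion
is non-decreasing across sweeps and iteration stops when a sweep gains less
than $10^{-8}$ (non-convergence returns the best iterate with a warning
carrying the criterion trace). Kaiser normalization can be disabled
(`kaiser_normalize = FALSE`). Manual rotation applies an exact Givens
rotation to one factor pair; "counterclockwise" is a positive angle with the
first factor on the abscissa, and every rotation is appended to a log so an
analysis can be replayed. Communalities are invariant under both rotations
to numerical precision.

**Scores, reliability, significance.** Defining sorts are flagged by the
threshold plus strict-majority rule (at most one factor per sort can hold a
strict majority). Factor z-scores weight each defining sort by
$w = f/(1-f^2)$ — the standard Q-methodology weighting, adopted because the
upstream analysis convention delegates it to standard Q software without
printing the formula — and standardize the weighted means across statements.
Factor arrays re-impose the grid on the z-scores. Composite reliability uses
the Spearman–Brown form $CR = 0.8p/(1+(p-1)0.8)$ with the per-sort
reliability fixed at 0.80; the z-score standard error is $\sqrt{1-CR}$ with
CR first rounded to three decimals — the rounding convention of standard
Q-analysis reports, which reproduces all four published
reliability/standard-error pairs exactly, while the unrounded form does not.
A statement distinguishes a factor at level $\alpha$ if its z-score differs
from *every* other factor's by more than
$z_\alpha\sqrt{SE_f^2 + SE_g^2}$ ($z_{0.05}=1.96$, $z_{0.01}=2.58$; marks
`D` and `D*`); consensus statements distinguish no factor and differ
non-significantly in every pairwise comparison. All boundary comparisons are
strict, so behavior at exact ties is deterministic.

## The synthetic corpus generator

The generator emulates the study conditions the pipeline was designed for:
institutions described by several short audit texts, with four latent
orientation types — interior-centric, layout-oriented, landscape-centered,
rehabilitation-driven — expressed as emphasis over 18 statement categories.
Defaults: 6–12 records per institution (matching the observed rate of
roughly nine audit images per institution in the motivating sample), 3–6
sentences per record, noise rate 0.1 (a sentence's category is drawn
uniformly instead of from the type's emphasis row with that probability),
and an emphasis matrix giving each type 75% of its mass uniformly over its
own category block and 25% over the rest, so every institution still
mentions every theme occasionally, as real audit text does.

Sentences are deterministic slot-filled templates with deliberately
category-specific vocabulary, so the hashed TF-IDF backend separates
categories without any model download. That is also the generator's main
departure from real data: real audit prose shares vocabulary across themes,
paraphrases freely, and varies in length and quality. Passing the recovery
tests therefore shows the pipeline's statistical machinery is sound — it
does *not* show that any particular embedding backend resolves real-world
semantic overlap. Ground truth is emitted beside the corpus, never inside
it.

Problem sizes used in the shipped tests and acceptance script — 200
institutions for recovery runs, 18 × 3 statements, 8 extracted factors —
were chosen as the smallest sizes at which the four-type structure is
comfortably identified; they keep a full pipeline run under half a minute.

## Design choices where the design was open

- **Record-level vs sentence-level clustering units:** sentences, since the
  statement set must consist of single sentences and segmentation is
  explicitly part of the pipeline. Corpus records store full texts;
  splitting happens in the statement builder.
- **K and statements-per-cluster are explicit parameters** (`k = 18`,
  `per_cluster = 3` defaults). The upstream workflow reports an automatic
  optimum of K = 4 alongside a final 18-partition, 54-statement set after
  human review; no automatic mapping between those is assumed.
- **Grid assignment by global ranking** rather than binned raw similarity:
  a forced distribution prescribes exact column counts, which only a global
  ranking can guarantee.
- **Joint K selection rule** (rank sum of silhouette and Davies–Bouldin,
  ties to smaller K): "jointly used" needs a concrete rule; rank aggregation
  treats both indices symmetrically and is scale-free.
- **Tie policies everywhere are index-based** for bit-reproducibility.

## Known limitations

- The default embedding is lexical: synonyms land in different buckets, so
  statement/institution similarity understates semantic overlap in real
  prose. Register a sentence-embedding backend for production corpora.
- The screen assumes the forced-grid invariants; free-distribution sorts are
  out of scope.
- Bipolar factors are not split, and oblique rotations, Humphrey's rule and
  parallel analysis are intentionally not provided.
- With fewer than two institutions per viewpoint no factor can be admitted;
  the error messages name the failing factor or cluster.

## A worked example

```{r example, eval = FALSE}
library(qorient)

gen <- generate_corpus(default_four_type_config(120, seed = 7))
build <- build_statements(gen$corpus, k = 18, seed = 7)
qsorts <- build_qsorts(gen$corpus, build$statements)
analysis <- q_analyze(qsorts)

glance(analysis)
analysis$reliability
score_recovery(analysis$flags, gen$truth)$match_rate
autoplot(analysis$unrotated)   # scree
tidy(analysis)                 # statement x factor z-scores, arrays, marks
```

The same stages run from the command line via the bundled CLI
(`inst/cli/qorient`), driven by a YAML configuration with flag overrides,
and `run_pipeline()` writes every artifact plus a checksummed manifest so a
rerun with an identical configuration is verifiably identical.
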