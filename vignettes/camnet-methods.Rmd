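---
title: "Models and methods behind camnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind camnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camnet)
```

# The data model

A cognitive-affective map (CAM) is one participant's belief network about a
topic. camnet represents it as a simple graph with typed attributes:

* a **concept** has free text, an optional comment, a position (screen
  pixels, origin top-left; stored but never analyzed), a `predefined` flag,
  and an affective **valence**: one of the seven integers −3..+3 or the
  distinct state *ambivalent*. Ambivalence is a marker, not a number — it is
  kept out of arithmetic by construction and only enters means under an
  explicit policy (below).
* a **connector** joins two distinct concepts with a signed strength in
  {−3..−1, +1..+3} (positive = supporting, negative = opposing) and may be
  directed. Zero strength does not exist; at most one connector joins a
  concept pair.

The canonical JSON serialization sorts keys and rows, so structurally equal
CAMs are byte-identical on disk — this is what makes the content-digest
protocol (below) possible. A legacy numeric ambivalent code (default 10, as
found in older Valence-style exports) is mapped to the marker at parse time;
the code is configurable because the historical encodings vary.

Validation against a *study configuration* mirrors the checks a collection
tool applies at save time (minimum concept count, per-concept word and
character limits, whether ambivalence/arrows/opposing connections were
enabled). Violations are returned as data, one row per broken rule, never as
exceptions: a batch of collected files should be triaged, not aborted.

## Ambivalence policy

Mean-type indicators need a number for ambivalent concepts. The package
default (`as_zero`) counts them as 0, which preserves the sample size and
reflects that ambivalence is affectively "both ways at once"; the
alternative (`exclude`) drops them. Share-type indicators always count
ambivalence as its own class, so `pct_positive + pct_negative + pct_neutral
+ pct_ambivalent = 1` exactly. Every function that averages valences exposes
the policy argument.

# Summarization operations

Raw concept texts are noisy: typos, synonyms, case and spacing variants.
All matching operations first normalize text (case-fold, trim, collapse
internal whitespace); the original text is preserved in a `raw_text` field
when a summary map rewrites it, so summarization is non-destructive and
idempotent.

* **OSA distance.** The optimal string alignment distance (restricted
  Damerau–Levenshtein: insert, delete, substitute, transpose adjacent, no
  substring edited twice) is implemented as the standard three-row dynamic
  program. OSA famously violates the triangle inequality ("ca" → "abc" is 3
  under OSA, 2 unrestricted), so the suite asserts symmetry and
  identity-of-indiscernibles but deliberately not the triangle inequality.
  Distance suggestions link pairs at distance ≤ `max_dist` (default 1, the
  single-typo radius) and report the connected components of the link graph
  — single-linkage closure, chosen so chains of spelling variants land in
  one group; the alternative (pairwise-only display) would fragment them.
* **Regex search** uses R's native engines, which support the POSIX classes
  (`[[:digit:]]` etc.) directly; matching is case-insensitive by default.
* **Synonym groups** operate on single-word texts only; two words link when
  their synonym sets (each including the word itself) intersect. The
  dictionary is a plain JSON map, symmetrized at load; a small English
  fixture ships with the package and real dictionaries plug in through the
  same format.
* **Embedding suggestions** take any text → vector table (CSV loader
  provided) and link pairs with cosine similarity ≥ threshold. No language
  model is bundled — the provider interface keeps the package offline and
  the tests deterministic. A 1e-9 tolerance on the threshold comparison
  lets exactly proportional vectors pass a threshold of 1.

# Inter-rater reliability on partitions

Raters code a sampled list of unique concepts into categories *using their
own vocabulary*. What should be reliable is the partition — do raters group
the same concepts together? — never the invented names. All coefficients
therefore run on an aligned label space and are property-tested to be
invariant under bijective renaming of any rater's categories.

Two alignment schemes are reported side by side:

* **perfect-match (`exact_overlap`)**: a rater's category maps onto a
  reference category only when the two contain exactly the same concepts.
  Under independent random coding no category matches, the marginals live in
  disjoint index spaces and κ is exactly 0 — strictly calibrated, but
  conservative under noise (one misfiled concept breaks the match).
* **assignment-optimal (`max_overlap`)**: a one-to-one assignment of
  categories maximizing the total number of overlapping items (weighted
  maximum bipartite matching, solved exactly). This is the natural measure
  of "how far can the partitions be reconciled", but because the alignment
  itself maximizes agreement it is slightly optimistic under the null of
  independent coding (about +0.07 at N = 200, four equiprobable
  categories). Reporting both brackets the truth; the report labels each.

With more than two raters, the rater with the most categories anchors the
shared space and the others are aligned to it sequentially; category order
is first-occurrence along the fixed item list, so every tie-break is
name-invariant. Cohen's κ uses the standard marginal chance correction;
the degenerate case p_e = 1 (one shared category) returns 1 for perfect
agreement and 0 otherwise rather than 0/0. Fleiss' κ and category-wise κ_j
follow the classical multi-rater formulas on the n_ij table of the aligned
space.

# Network indicators

Arrow direction is ignored for all distance and degree computations (the
undirected projection), matching the convention that a connector's incident
count is its degree regardless of orientation; the directed structure stays
in the data model. Density is m/(n(n−1)/2), undefined for n = 1. The
diameter of a disconnected CAM is computed on the largest component and
flagged, avoiding infinities. The central concept is resolved as: explicit
id > predefined concepts (by degree, then id) > maximum degree (ties by
id) — study designs usually predefine the central topic concept.

Communities (mezzo level) come from greedy modularity maximization with the
merge path cut explicitly at its maximum-modularity step and community ids
renumbered by smallest member id, making the output deterministic.

## Neighborhood valences

Six variants summarize the affect around a focal concept, on the graph
after optional temporary removal of connectors/concepts (so a bridge to an
opposing cluster does not contaminate the statistic). With N1 the adjacent
concepts and N2 those at distance ≤ 2 (focus excluded):

1. plain mean over N1; 2. plain mean over N2;
3. mean over N1 weighted by |strength| of the incident connector;
4. mean over N2 weighted by the maximum over shortest paths of the product
   of |strength|/3 along the path (so weight decays with distance and weak
   links);
5. affect-adjusted mean over N1: the numerator sums all numeric valences,
   the denominator counts only affect-carrying (non-neutral, non-ambivalent)
   neighbors; 6. the same over N2.

The affect adjustment in variants 5/6 is one defensible reading of
"adjustment for positive concepts": neutral padding concepts stop diluting
the signal while every neighbor still contributes its value. The variant
registry names each output, and the implementation is a single dispatch
point so an alternative adjustment can be swapped without touching callers.
Empty neighborhoods (and carrier-free ones for 5/6) return `NA` flagged
`undefined` rather than 0, which would fake neutrality.

# Aggregation, co-occurrence, clustering, slicing

**Canonical adjacency.** Aggregation matches concepts across CAMs by exact
normalized label, so it is meant to run *after* summarization. Within a CAM,
duplicate labels are first disambiguated to `label_1, label_2, …` in
descending degree order (ties by concept id). A node's frequency counts
contributing CAMs (not instances), an edge's frequency counts CAMs drawing
that pair connected in any direction or sign; mean valence and mean strength
ride along as auxiliary attributes. Frequencies, not strengths, drive the
exported node sizes and edge widths.

**Co-occurrence.** Presence is binary per CAM. For a pair of concepts the
2×2 table (a = both, b/c = one only, d = neither) yields
φ = (ad − bc)/√[(a+b)(c+d)(a+c)(b+d)] with the 1-df χ² = Nφ² p-value
(no continuity correction, preserving the identity); Fisher's exact p is
reported alongside whenever an expected cell drops below 5. Raw p-values
are not multiplicity-adjusted; a Benjamini–Hochberg column is included in
the matrix output for users who want it. This is a deliberate, documented
limitation: the matrix is exploratory.

**Valence clustering.** For every concept drawn at least twice, the per-CAM
mean valence forms a CAM × concept feature matrix; columns are z-scored over
the CAMs that drew the concept, then missing entries are imputed at the
grand mean (0 after the transform) and flagged per cell. Clustering is
agglomerative with Euclidean distance and Ward's method (`ward.D2`); the
objects clustered are CAMs (the question is "which participants share an
affective profile"), with a `transpose` switch to cluster concepts instead.
Imputing after the z-transform keeps absent concepts exactly neutral in
every column regardless of that column's scale; imputing before would drag
column means toward the imputation value.

**Slicing.** Deletion targets are addressed by concept text so one spec
applies to every participant's CAM; ambiguous duplicate texts are an error
that points to canonical renaming. The verdict is PASS iff the component
count equals the expectation, every anchor resolves to a distinct component,
and no component falls below the minimum size. The paired component
comparison reports the within-subject t on component mean valences with
effect size d_z = mean(diff)/sd(diff); zero-variance differences are
undefined, not 0 or ±∞.

# The analysis protocol

Every pipeline step can be recorded as an append-only JSON-lines entry:
operation name, full parameter snapshot (seeds included), md5 digests of the
consumed and produced objects, a timestamp, and a rolling hash chaining the
entry to its predecessor. Timestamps are excluded from the hashes so replay
verdicts ignore wall-clock. Replay re-executes each recorded operation with
its recorded parameters against an object store keyed by content digest:
the verdict is PASS iff every input is found and every recomputed output
digest matches. Any mutation — an edited map row, a swapped input file, a
rewritten entry — surfaces as a FAIL naming the first diverging step, or as
a broken chain on read.

# The synthetic generator

The generator emulates the structural regimes that predefined starting
concepts induce in real studies: a single central concept yields a **star**;
two opposing predefined concepts yield **two clusters** joined by one
opposing bridge (strengths uniform in {+1..+3} within clusters, {−3..−1} on
the bridge); a predefined root yields a random recursive **tree**; no
predefined structure yields a connected **mesh**. Valences follow a
two-level model: each CAM draws a latent attitude μ ~ Normal(μ₀, τ), each
concept a valence clip(round(Normal(μ, σ)), −3, 3), with an independent
coin flip (default 0.05) overriding the draw by the ambivalent marker.
Defaults (8–16 concepts, τ = σ = 1, μ₀ = 0) are in the range of published
CAM studies of moderate size. A length-2 μ₀ plants two attitude groups for
clustering-recovery checks. Each CAM derives its own random stream from
(seed, index), so enlarging a set never perturbs existing CAMs.

Planted text noise replaces a recorded fraction of texts by typos (exactly
one adjacent transposition or substitution, OSA distance 1) or dictionary
synonyms, returning the planted pairs for recovery scoring.

What the generator does *not* emulate: drawing order and paradata, multi-word
free text of realistic length, semantic correlation between neighboring
concepts beyond the cluster valence shift, and participant-specific
vocabulary. Tests passing on synthetic sets therefore certify the
*computational* pipeline — they say nothing about the validity of the
indicators on human data.

# Numerical choices and problem sizes

* Oracle-equivalence tests run every graph statistic against brute-force
  re-derivations (Floyd–Warshall, exhaustive shortest-path enumeration,
  flood fill, set scans) on 200 random CAMs of ≤ 8 nodes — small enough for
  exhaustive enumeration, large enough to hit every degenerate shape
  (isolates, multi-component graphs, ties).
* Kappa calibration uses 500 replicates of two independent coders on 200
  items and 4 categories; the φ–χ² identity uses 1000 random tables at
  tolerance 1e-10; recovery checks use 30–200 seeded CAMs per scenario.
  These sizes keep the full suite around a minute on one CPU while leaving
  Monte-Carlo error well inside the asserted bands.
* All stochastic tests fix seeds; generator streams are derived per CAM as
  (seed × 48271 + index × 16807) mod (2³¹ − 1).

# Known limitations

* The 33-indicator parity of the original interactive tooling is not
  promised; the registry implements the documented core set and is
  extensible.
* Correlations between indicators are reported with plain two-sided
  p-values, without multiplicity control.
* exact_overlap reliability is conservative and max_overlap optimistic
  under the null; report both, and prefer Fleiss' κ for a single headline
  number.
* Co-occurrence φ needs all four marginals positive; pairs failing that are
  flagged undefined rather than forced to 0.
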