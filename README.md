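# camnet

Analysis of cognitive-affective maps (CAMs) in R.

CAMs are participant-drawn belief networks: each **concept** carries free
text and an affective **valence** on the integer scale −3 (strongly
negative) to +3 (strongly positive), with 0 = neutral and a distinct
*ambivalent* state; **connectors** between concepts carry a signed strength
in {−3..−1, +1..+3} (positive = supporting, negative = opposing) and may be
directed. A CAM is thus a weighted, optionally directed simple graph, and a
CAM study yields one such graph per participant. Researchers in psychology
and adjacent fields use CAMs to elicit attitudes and belief systems about a
topic (a technology, a policy, a crisis) and need tooling for the whole
pipeline from raw drawings to reportable statistics.

camnet implements that pipeline as a scriptable library plus a thin CLI:

- **Data model** — canonical CAM JSON with strict invariants (unique ids,
  simple graph, valence ranges), validation against a study configuration
  (minimum concept count, word/character limits, feature switches),
  edge-list/GraphML export.
- **Summarization** — computer-assisted grouping of raw concept texts under
  superordinate categories: optimal string alignment (OSA) distance for
  spelling variants (`osa_distance("dreams", "dreasm") == 1`), regular
  expression search (POSIX classes supported), synonym-dictionary overlap,
  word-vector cosine similarity with a pluggable vector-table provider, and
  an overview of not-yet-summarized concepts.
- **Inter-rater reliability** — coefficients computed on the *partition
  structure* of independent raters' codings, invariant to the category
  names each rater invents: pairwise Cohen's κ = (p_o − p_e)/(1 − p_e)
  under two alignment schemes (perfect-match and assignment-optimal), plus
  Fleiss' κ with category-wise coefficients.
- **Network indicators** — macro (mean valence, central node valence,
  density, diameter, node/link counts, valence-class shares), micro
  (degree, betweenness, closeness, valence), mezzo (greedy-modularity
  communities), and six neighborhood-valence variants over order-1/2
  neighborhoods with plain, |strength|-weighted and affect-adjusted means,
  with temporary edge/concept removal.
- **Aggregation** — the canonical adjacency matrix across CAMs: within-CAM
  duplicate labels renamed `label_1, label_2, …` by descending degree, node
  and edge weights equal to drawing frequencies.
- **Co-occurrence** — per-CAM presence contingency tables and
  φ = (ad − bc)/√[(a+b)(c+d)(a+c)(b+d)] with χ² = Nφ² p-values, plus
  hierarchical clustering (Euclidean distance, Ward's method) of CAMs by
  z-scored concept valence profiles.
- **Slicing** — splitting CAMs into sub-CAMs by deleting named connectors
  or concepts, with component-count/anchor validation and paired t
  comparison of the resulting components.
- **Protocol** — an append-only, hash-chained record of every analysis
  step with deterministic replay, so a summarization can be verified end
  to end.
- **Synthetic generator** — seeded CAM sets with star / two-cluster / tree
  / mesh topologies, a latent-attitude valence model and planted text noise,
  used throughout the test suite.

## Worked example

```r
library(camnet)

# a synthetic two-cluster study: 20 participants, two opposing predefined
# anchor concepts, everything seeded
syn  <- generate_cam_set(gen_config(n_cams = 20, topology = "two_cluster",
                                    seed = 7))
cams <- syn$cams

# summarize two raw texts under one category and compute macro indicators
cams <- apply_summary(cams, summary_map(c(cost = "Money", price = "Money")))
macro_indicators(cams$cams[[1]])
#> # A tibble: 10 x 5
#>    cam_id   indicator            level focus   value
#>    <chr>    <chr>                <chr> <chr>   <dbl>
#>  1 cam_0001 mean_valence         macro ""     0.231
#>  2 cam_0001 central_node_valence macro ""     2
#>  3 cam_0001 density              macro ""     0.154
#>  4 cam_0001 diameter             macro ""     7
#>  5 cam_0001 num_nodes            macro ""    13
#> # ... pct_positive / pct_negative / pct_neutral / pct_ambivalent
```

`mean_valence` is the CAM's average affect (ambivalent counted as 0),
`density` the realized fraction of possible connections, and the `pct_*`
rows the share of each valence class; together they describe how positive,
how elaborated and how conflicted one participant's belief network is.

Slicing the same CAMs at the bridge between the two anchors and comparing
the halves within participants:

```r
spec <- slice_spec(edges_to_delete = list(cams$cams[[1]]$concepts$text[1:2]),
                   expected_components = 2,
                   anchors = c(A = cams$cams[[1]]$concepts$text[1],
                               B = cams$cams[[1]]$concepts$text[2]))
sl <- slice_cam(cams$cams[[1]], spec)
sl$verdict        # "PASS" -- exactly 2 components, both anchors resolved
```

The CLI mirrors the library (`cam synth`, `cam validate`, `cam suggest`,
`cam report`, …); see `inst/exec/cam` and `cam_main(c("--help"))`.

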