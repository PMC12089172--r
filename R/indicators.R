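#' Numeric valence under an ambivalence policy
#'
#' Ambivalent concepts carry simultaneous positive and negative affect and
#' have no numeric rating. For averaging they are either treated as 0
#' (`as_zero`, the default) or excluded (`exclude`, yielding `NA`).
#' Percentage-type indicators always count ambivalence as its own class.
#'
#' @param valence Integer vector (`NA` for ambivalent concepts).
#' @param ambivalent Logical vector.
#' @param policy `"as_zero"` or `"exclude"`.
#' @return Numeric vector (`NA` marks excluded concepts).
#' @export
numeric_valence <- function(valence, ambivalent, policy = c("as_zero", "exclude")) {
  policy <- match.arg(policy)
  v <- as.numeric(valence)
  if (policy == "as_zero") v[ambivalent] <- 0 else v[ambivalent] <- NA_real_
  v
}

indicator_row <- function(cam_id, indicator, level, focus, value) {
  tibble::tibble(cam_id = cam_id, indicator = indicator, level = level,
                 focus = focus, value = as.numeric(value))
}

# central concept: explicit id > predefined flag > max degree; ties broken by
# max degree then lexicographic id
central_concept <- function(x, central_id = NULL) {
  co <- x$concepts
  deg <- igraph::degree(cam_igraph(x))
  cand <- if (!is.null(central_id)) {
    if (!central_id %in% co$id)
      stop_camnet(paste("unknown concept id:", central_id), "camnet_integrity_error")
    central_id
  } else if (any(co$predefined)) co$id[co$predefined] else co$id
  cand[order(-deg[cand], cand)][1L]
}

#' Macro-level network indicators of a CAM
#'
#' Whole-CAM indicators: mean valence, central node valence, density,
#' diameter, number of nodes/links, and the share of positive, negative,
#' neutral and ambivalent concepts. Density is `m / (n(n-1)/2)` on the
#' undirected simple projection (`NA` for a single-node CAM); the diameter is
#' the longest unweighted shortest path on the largest connected component
#' (flagged via the `diameter_on_largest_component` attribute when the CAM is
#' disconnected).
#'
#' @param x A `cam` with at least one concept.
#' @param central_id Optional explicit central concept id; otherwise a
#'   predefined concept (ties by degree then id), else the highest-degree
#'   concept.
#' @param ambivalent_policy Policy for mean valence (see [numeric_valence()]).
#' @return A long tibble (`cam_id`, `indicator`, `level = "macro"`, `focus`,
#'   `value`).
#' @export
macro_indicators <- function(x, central_id = NULL, ambivalent_policy = "as_zero") {
  stopifnot(inherits(x, "cam"))
  co <- x$concepts
  n <- nrow(co)
  if (n == 0L) stop_camnet("CAM has no concepts", "camnet_integrity_error")
  m <- nrow(x$connectors)
  g <- cam_igraph(x, ambivalent_policy)
  v <- numeric_valence(co$valence, co$ambivalent, ambivalent_policy)
  comp <- igraph::components(g)
  largest <- which(comp$membership == which.max(comp$csize))
  diam <- if (length(largest) == 1L) 0 else
    igraph::diameter(igraph::induced_subgraph(g, largest), weights = NA)
  cls <- valence_class(co$valence, co$ambivalent)
  central <- central_concept(x, central_id)
  rows <- indicator_row(
    x$cam_id,
    c("mean_valence", "central_node_valence", "density", "diameter",
      "num_nodes", "num_links", "pct_positive", "pct_negative",
      "pct_neutral", "pct_ambivalent"),
    "macro", "",
    c(mean(v, na.rm = TRUE),
      numeric_valence(co$valence[co$id == central], co$ambivalent[co$id == central],
                      ambivalent_policy),
      if (n > 1L) m / (n * (n - 1) / 2) else NA_real_,
      diam, n, m,
      mean(cls == "positive"), mean(cls == "negative"),
      mean(cls == "neutral"), mean(cls == "ambivalent")))
  attr(rows, "diameter_on_largest_component") <- comp$no > 1L
  rows
}

#' Micro-level indicators for selected concepts
#'
#' Per focal concept: degree (undirected incident connectors; in- and
#' out-degree are not distinguished), betweenness centrality, closeness
#' centrality within the concept's connected component, and the concept's own
#' valence.
#'
#' @param x A `cam`.
#' @param focus Character vector of concept ids.
#' @param ambivalent_policy Policy for the reported valence.
#' @return A long tibble (`cam_id`, `indicator`, `level = "micro"`, `focus`,
#'   `value`).
#' @export
micro_indicators <- function(x, focus, ambivalent_policy = "as_zero") {
  stopifnot(inherits(x, "cam"))
  unknown <- setdiff(focus, x$concepts$id)
  if (length(unknown))
    stop_camnet(paste("unknown concept id(s):", paste(unknown, collapse = ", ")),
                "camnet_integrity_error")
  g <- cam_igraph(x, ambivalent_policy)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  comp <- igraph::components(g)
  clo <- numeric(igraph::vcount(g))
  names(clo) <- igraph::V(g)$name
  for (k in seq_len(comp$no)) {
    memb <- which(comp$membership == k)
    sub <- igraph::induced_subgraph(g, memb)
    clo[igraph::V(sub)$name] <- if (length(memb) == 1L) NA_real_ else
      igraph::closeness(sub, weights = NA)
  }
  val <- setNames(igraph::V(g)$valence, igraph::V(g)$name)
  dplyr::bind_rows(lapply(focus, function(id) {
    indicator_row(x$cam_id, c("degree", "betweenness", "closeness", "valence"),
                  "micro", id, c(deg[id], btw[id], clo[id], val[id]))
  }))
}

#' Mezzo-level (community) indicators
#'
#' Partitions the undirected projection by greedy modularity maximization and
#' reports, per community, its size, mean valence and internal density, plus
#' the number of connected components of the CAM. Community ids are renumbered
#' by their smallest member concept id, so the output is deterministic.
#'
#' @param x A `cam` with at least 2 concepts.
#' @param ambivalent_policy Policy for mean valences.
#' @return A long tibble (`cam_id`, `indicator`, `level = "mezzo"`, `focus` =
#'   community id or `""`, `value`).
#' @export
mezzo_indicators <- function(x, ambivalent_policy = "as_zero") {
  stopifnot(inherits(x, "cam"), nrow(x$concepts) >= 2L)
  g <- cam_igraph(x, ambivalent_policy)
  comm <- igraph::cluster_fast_greedy(g, weights = NULL)
  # cut the greedy merge path at its maximum-modularity step explicitly
  n_comm <- igraph::vcount(g) - which.max(comm$modularity) + 1L
  memb <- if (n_comm >= igraph::vcount(g)) igraph::membership(comm) else
    igraph::cut_at(comm, no = n_comm)
  names(memb) <- igraph::V(g)$name
  first_member <- vapply(split(names(memb), memb),
                         function(v) min(v), character(1))
  # renumber communities by ascending smallest member id
  ord <- order(first_member)
  new_id <- integer(length(first_member))
  new_id[ord] <- seq_along(ord)
  rows <- list()
  for (old in seq_along(first_member)) {
    ids <- names(memb)[memb == old]
    sub <- igraph::induced_subgraph(g, ids)
    nn <- length(ids)
    dens <- if (nn > 1L) igraph::ecount(sub) / (nn * (nn - 1) / 2) else NA_real_
    rows[[length(rows) + 1L]] <- indicator_row(
      x$cam_id, c("community_size", "community_mean_valence", "community_density"),
      "mezzo", paste0("community_", new_id[old]),
      c(nn, mean(igraph::V(sub)$valence, na.rm = TRUE), dens))
  }
  rows[[length(rows) + 1L]] <- indicator_row(
    x$cam_id, "num_components", "mezzo", "", igraph::components(g)$no)
  out <- dplyr::bind_rows(rows)
  out[order(out$focus, out$indicator), ]
}

#' Neighborhood-valence indicators (six variants)
#'
#' Mean valences over the order-1 or order-2 neighborhood of a focal concept,
#' computed on the undirected projection after optional temporary removal of
#' connectors and/or concepts (so a bridge to an opposing cluster does not
#' distort the statistic). With N1 the concepts adjacent to the focus and N2
#' the concepts at distance <= 2 (both excluding the focus):
#'
#' * `1` plain mean valence over N1;
#' * `2` plain mean over N2;
#' * `3` weight of each N1 neighbor = |strength| of its connector to the
#'   focus; weighted mean;
#' * `4` weight of each N2 concept = max over unweighted shortest paths of the
#'   product of |strength|/3 along the path; weighted mean;
#' * `5` affect-adjusted mean over N1: numerator sums all numeric valences,
#'   denominator counts only affect-carrying (non-neutral, non-ambivalent)
#'   concepts;
#' * `6` affect-adjusted mean over N2.
#'
#' An empty neighborhood (or, for variants 5/6, no affect-carrying neighbor)
#' yields `NA` with attribute `undefined = TRUE`.
#'
#' @param x A `cam`.
#' @param focus A concept id; must survive the removals.
#' @param variant Integer 1..6.
#' @param removed_edges Optional list/matrix of concept-id pairs whose
#'   connectors are removed before the computation.
#' @param removed_nodes Optional character vector of concept ids removed
#'   before the computation.
#' @param ambivalent_policy Policy for numeric valences (default `as_zero`).
#' @return A single numeric value in `[-3, 3]`, or `NA` when undefined.
#' @export
neighborhood_valence <- function(x, focus, variant,
                                 removed_edges = NULL, removed_nodes = NULL,
                                 ambivalent_policy = "as_zero") {
  stopifnot(inherits(x, "cam"), variant %in% 1:6)
  if (!is.null(removed_nodes) && focus %in% removed_nodes)
    stop_camnet("focus concept was removed", "camnet_integrity_error")
  if (!focus %in% x$concepts$id)
    stop_camnet(paste("unknown concept id:", focus), "camnet_integrity_error")
  g <- cam_igraph(x, ambivalent_policy)
  if (!is.null(removed_edges)) {
    if (is.matrix(removed_edges))
      removed_edges <- lapply(seq_len(nrow(removed_edges)),
                              function(i) removed_edges[i, ])
    for (pr in removed_edges) {
      eid <- igraph::get_edge_ids(g, pr)
      eid <- eid[eid > 0]
      if (length(eid)) g <- igraph::delete_edges(g, eid)
    }
  }
  if (!is.null(removed_nodes)) {
    g <- igraph::delete_vertices(g, intersect(removed_nodes, igraph::V(g)$name))
  }
  dists <- igraph::distances(g, v = focus, weights = NA)[1L, ]
  order_k <- if (variant %in% c(1L, 3L, 5L)) 1 else 2
  nb <- names(dists)[dists >= 1 & dists <= order_k]
  if (!length(nb)) return(structure(NA_real_, undefined = TRUE))
  val <- setNames(igraph::V(g)$valence, igraph::V(g)$name)[nb]
  amb <- setNames(igraph::V(g)$ambivalent, igraph::V(g)$name)[nb]
  if (variant %in% c(1L, 2L)) return(mean(val, na.rm = TRUE))
  if (variant == 3L) {
    w <- vapply(nb, function(id) {
      eid <- igraph::get_edge_ids(g, c(focus, id))
      abs(igraph::E(g)$strength[eid])
    }, numeric(1))
    return(sum(w * val) / sum(w))
  }
  if (variant == 4L) {
    w <- vapply(nb, function(id) {
      paths <- igraph::all_shortest_paths(g, from = focus, to = id, weights = NA)$res
      max(vapply(paths, function(p) {
        vp <- as.integer(p)
        s <- 1
        for (k in seq_len(length(vp) - 1L)) {
          eid <- igraph::get_edge_ids(g, c(vp[k], vp[k + 1L]))
          s <- s * abs(igraph::E(g)$strength[eid]) / 3
        }
        s
      }, numeric(1)))
    }, numeric(1))
    return(sum(w * val) / sum(w))
  }
  # variants 5/6: affect-adjusted denominator
  carriers <- sum(!amb & !is.na(val) & val != 0)
  if (carriers == 0L) return(structure(NA_real_, undefined = TRUE))
  sum(val, na.rm = TRUE) / carriers
}

#' Indicator summary across a CAM set
#'
#' Per-indicator mean and SD over the CAMs of a set, plus the Pearson
#' correlation matrix between macro indicators (with plain two-sided p-values;
#' no multiplicity adjustment -- documented limitation).
#'
#' @param cams A `cam_set`.
#' @param central_id,ambivalent_policy Passed to [macro_indicators()].
#' @return A list with `per_cam` (long tibble), `summary` (indicator, mean,
#'   sd, n) and `correlations` (long tibble: indicator_a, indicator_b, r, p).
#' @export
indicator_summary <- function(cams, central_id = NULL, ambivalent_policy = "as_zero") {
  stopifnot(inherits(cams, "cam_set"))
  per_cam <- dplyr::bind_rows(lapply(cams$cams, macro_indicators,
                                     central_id = central_id,
                                     ambivalent_policy = ambivalent_policy))
  summ <- per_cam |>
    dplyr::group_by(.data$indicator) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = sd(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop")
  wide <- tidyr::pivot_wider(per_cam[, c("cam_id", "indicator", "value")],
                             names_from = "indicator", values_from = "value")
  inds <- setdiff(names(wide), "cam_id")
  cors <- list()
  if (nrow(wide) >= 3L) {
    for (i in seq_along(inds)) for (j in seq_along(inds)) {
      if (j <= i) next
      a <- wide[[inds[i]]]; b <- wide[[inds[j]]]
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) >= 3L && sd(a[ok]) > 0 && sd(b[ok]) > 0) {
        ct <- stats::cor.test(a[ok], b[ok])
        cors[[length(cors) + 1L]] <- tibble::tibble(
          indicator_a = inds[i], indicator_b = inds[j],
          r = unname(ct$estimate), p = ct$p.value)
      }
    }
  }
  list(per_cam = per_cam, summary = summ,
       correlations = if (length(cors)) dplyr::bind_rows(cors) else
         tibble::tibble(indicator_a = character(), indicator_b = character(),
                        r = numeric(), p = numeric()))
}
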