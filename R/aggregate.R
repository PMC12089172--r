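#' Rename duplicate concept texts within a CAM
#'
#' Aggregation across CAMs matches concepts by exact (normalized) text, so
#' duplicate texts inside one CAM must first be disambiguated: identical texts
#' get suffixes `_1`, `_2`, ... in descending order of degree, degree ties
#' broken by ascending concept id. Unique texts are left untouched, which
#' makes the operation idempotent.
#'
#' @param x A `cam`.
#' @return A `cam` with disambiguated concept texts.
#' @export
canonicalize_cam <- function(x) {
  stopifnot(inherits(x, "cam"))
  co <- x$concepts
  if (!"raw_text" %in% names(co)) co$raw_text <- co$text
  key <- normalize_text(co$text)
  deg <- igraph::degree(cam_igraph(x))[co$id]
  for (txt in unique(key[duplicated(key)])) {
    idx <- which(key == txt)
    idx <- idx[order(-deg[idx], co$id[idx])]
    co$text[idx] <- paste0(co$text[idx], "_", seq_along(idx))
  }
  x$concepts <- co
  x
}

#' Select CAMs for aggregation
#'
#' @param cams A `cam_set`.
#' @param mode `"random_k"` (seeded random subset), `"most_positive_k"` /
#'   `"most_negative_k"` (ranked by macro mean valence, ties by `cam_id`), or
#'   `"by_ids"`.
#' @param k Number of CAMs for the `_k` modes.
#' @param ids CAM ids for `by_ids`.
#' @param seed Integer seed for `random_k`.
#' @return A `cam_set` with the selected CAMs (selection order preserved).
#' @export
select_cams <- function(cams, mode = c("random_k", "most_positive_k",
                                       "most_negative_k", "by_ids"),
                        k = NULL, ids = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(cams, "cam_set"))
  all_ids <- vapply(cams$cams, `[[`, character(1), "cam_id")
  pick <- switch(mode,
    by_ids = {
      unknown <- setdiff(ids, all_ids)
      if (length(unknown))
        stop_camnet(paste("unknown cam id(s):", paste(unknown, collapse = ", ")),
                    "camnet_integrity_error")
      ids
    },
    random_k = {
      stopifnot(!is.null(k), k <= length(all_ids))
      withr::with_seed(as.integer(seed), sample(all_ids, k))
    },
    {
      stopifnot(!is.null(k), k <= length(all_ids))
      mv <- vapply(cams$cams, function(cm) {
        mi <- macro_indicators(cm)
        mi$value[mi$indicator == "mean_valence"]
      }, numeric(1))
      sgn <- if (mode == "most_positive_k") -1 else 1
      all_ids[order(sgn * mv, all_ids)][seq_len(k)]
    })
  cam_set(cams$cams[pick], provenance = cams$provenance)
}

#' Aggregate CAMs into a canonical adjacency graph
#'
#' Builds the cross-CAM aggregate ("canonical adjacency matrix"): nodes are
#' the union of canonical concept labels; a node's frequency is the number of
#' contributing CAMs that drew that label, its valence the mean numeric
#' valence over contributors; an edge's frequency is the number of CAMs that
#' drew a connector between the two labels (any sign or direction). Each CAM
#' is canonicalized (see [canonicalize_cam()]) before counting; aggregation is
#' intended to run after summarization, since matching is exact on labels.
#'
#' @param cams A non-empty `cam_set` (typically a [select_cams()] result).
#' @param ambivalent_policy Policy for mean valences.
#' @return An object of class `cam_aggregate`: `nodes` (tibble `label`,
#'   `frequency`, `mean_valence`), `edges` (tibble `label_a`, `label_b`,
#'   `frequency`, `mean_strength`), `n_cams`.
#' @export
aggregate_cams <- function(cams, ambivalent_policy = "as_zero") {
  stopifnot(inherits(cams, "cam_set"))
  if (!length(cams$cams)) stop_camnet("empty CAM selection", "camnet_integrity_error")
  canon <- lapply(cams$cams, canonicalize_cam)
  node_rows <- dplyr::bind_rows(lapply(canon, function(cm) {
    co <- cm$concepts
    tibble::tibble(cam_id = cm$cam_id, label = normalize_text(co$text),
                   valence = numeric_valence(co$valence, co$ambivalent,
                                             ambivalent_policy))
  }))
  nodes <- node_rows |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(frequency = dplyr::n_distinct(.data$cam_id),
                     mean_valence = mean(.data$valence, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(.data$label)
  edge_rows <- dplyr::bind_rows(lapply(canon, function(cm) {
    cn <- cm$connectors
    if (!nrow(cn)) return(NULL)
    lab <- setNames(normalize_text(cm$concepts$text), cm$concepts$id)
    a <- unname(lab[cn$source]); b <- unname(lab[cn$target])
    tibble::tibble(cam_id = cm$cam_id,
                   label_a = pmin(a, b), label_b = pmax(a, b),
                   strength = cn$strength)
  }))
  edges <- if (is.null(edge_rows) || !nrow(edge_rows)) {
    tibble::tibble(label_a = character(), label_b = character(),
                   frequency = integer(), mean_strength = numeric())
  } else {
    edge_rows |>
      dplyr::group_by(.data$label_a, .data$label_b) |>
      dplyr::summarise(frequency = dplyr::n_distinct(.data$cam_id),
                       mean_strength = mean(.data$strength), .groups = "drop") |>
      dplyr::arrange(.data$label_a, .data$label_b)
  }
  structure(list(nodes = nodes, edges = edges, n_cams = length(cams$cams)),
            class = "cam_aggregate")
}

#' @export
print.cam_aggregate <- function(x, ...) {
  cat(sprintf("<cam_aggregate> %d CAMs -> %d canonical nodes, %d edges\n",
              x$n_cams, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Adjacency matrix of an aggregate graph
#'
#' @param agg A `cam_aggregate`.
#' @return A symmetric integer matrix of edge frequencies with canonical
#'   labels as dimnames.
#' @export
aggregate_adjacency <- function(agg) {
  stopifnot(inherits(agg, "cam_aggregate"))
  labs <- agg$nodes$label
  m <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  if (nrow(agg$edges)) for (i in seq_len(nrow(agg$edges))) {
    a <- agg$edges$label_a[i]; b <- agg$edges$label_b[i]
    m[a, b] <- m[b, a] <- agg$edges$frequency[i]
  }
  m
}

aggregate_igraph <- function(agg) {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(agg$nodes), name = agg$nodes$label,
                            frequency = agg$nodes$frequency,
                            mean_valence = agg$nodes$mean_valence,
                            size = agg$nodes$frequency)
  if (nrow(agg$edges)) {
    g <- igraph::add_edges(g, rbind(match(agg$edges$label_a, agg$nodes$label),
                                    match(agg$edges$label_b, agg$nodes$label)),
                           frequency = agg$edges$frequency,
                           mean_strength = agg$edges$mean_strength,
                           width = agg$edges$frequency)
  }
  g
}

#' Export an aggregate graph
#'
#' Writes GraphML or DOT with node `size` and edge `width` attributes
#' proportional to drawing frequency, consumable by standard graph viewers.
#'
#' @param agg A `cam_aggregate`.
#' @param path Output file path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_aggregate_graph <- function(agg, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(aggregate_igraph(agg), path, format = format)
  invisible(path)
}
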