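#' Specification of a CAM slicing operation
#'
#' Slicing splits a CAM into sub-CAMs by deleting named connectors and/or
#' concepts (e.g. cutting the bridge between two predefined opposing concepts
#' such as "own car" and "public transport"). Deletion targets are addressed
#' by concept text (after summarization) so the same spec applies across all
#' participants' CAMs.
#'
#' @param edges_to_delete List of length-2 character vectors: unordered text
#'   pairs whose connector is deleted.
#' @param nodes_to_delete Character vector of concept texts to delete.
#' @param expected_components Positive integer: the number of components the
#'   sliced CAM must fall into for the slicing to validate.
#' @param anchors Optional named character vector: component name -> anchor
#'   concept text; each named component must contain its anchor.
#' @param min_component_size Minimum concept count per component (default 1).
#' @return An object of class `slice_spec`.
#' @export
slice_spec <- function(edges_to_delete = list(), nodes_to_delete = character(),
                       expected_components, anchors = NULL,
                       min_component_size = 1L) {
  if (is.character(edges_to_delete) && length(edges_to_delete) == 2L)
    edges_to_delete <- list(edges_to_delete)
  if (!length(edges_to_delete) && !length(nodes_to_delete))
    stop_camnet("slice spec must delete at least one connector or concept",
                "camnet_slice_error")
  stopifnot(expected_components >= 1L)
  if (!is.null(anchors)) {
    stopifnot(!is.null(names(anchors)), all(nzchar(names(anchors))))
    if (anyDuplicated(normalize_text(anchors)))
      stop_camnet("anchor concepts must be distinct", "camnet_slice_error")
  }
  structure(list(edges_to_delete = lapply(edges_to_delete, normalize_text),
                 nodes_to_delete = normalize_text(nodes_to_delete),
                 expected_components = as.integer(expected_components),
                 anchors = if (is.null(anchors)) NULL else
                   setNames(normalize_text(anchors), names(anchors)),
                 min_component_size = as.integer(min_component_size)),
            class = "slice_spec")
}

# resolve a concept text to a single concept id; ambiguity is an error so the
# caller canonicalizes duplicate labels first
resolve_text <- function(x, txt) {
  key <- normalize_text(x$concepts$text)
  hits <- x$concepts$id[key == txt]
  if (!length(hits)) {
    cand <- head(sort(unique(key)), 10L)
    stop_camnet(sprintf("concept '%s' not found in CAM %s; candidates: %s",
                        txt, x$cam_id, paste(cand, collapse = ", ")),
                "camnet_slice_error")
  }
  if (length(hits) > 1L)
    stop_camnet(sprintf(
      "concept text '%s' is ambiguous in CAM %s; canonicalize duplicate labels first",
      txt, x$cam_id), "camnet_slice_error")
  hits
}

#' Slice a CAM into sub-CAMs
#'
#' Applies the deletions of a [slice_spec()], computes the connected
#' components of the undirected projection, and validates the result: the
#' component count must equal `expected_components`, every anchor (if given)
#' must resolve to a distinct component, and every component must reach the
#' minimum size. The input CAM is never modified.
#'
#' @param x A `cam`.
#' @param spec A `slice_spec`.
#' @return A list of class `cam_slice`: `verdict` (`"PASS"`/`"FAIL"`),
#'   `n_components`, `sub_cams` (named list of standalone `cam` objects,
#'   cam_id suffixed by component name), `reasons` (character, empty on
#'   PASS).
#' @export
slice_cam <- function(x, spec) {
  stopifnot(inherits(x, "cam"), inherits(spec, "slice_spec"))
  cn <- x$connectors
  co <- x$concepts
  drop_edge <- logical(nrow(cn))
  for (pr in spec$edges_to_delete) {
    ids <- c(resolve_text(x, pr[1L]), resolve_text(x, pr[2L]))
    drop_edge <- drop_edge |
      (cn$source %in% ids & cn$target %in% ids)
  }
  drop_node_ids <- vapply(spec$nodes_to_delete, function(t) resolve_text(x, t),
                          character(1))
  keep_co <- !co$id %in% drop_node_ids
  cn2 <- cn[!drop_edge & !(cn$source %in% drop_node_ids) &
              !(cn$target %in% drop_node_ids), ]
  co2 <- co[keep_co, ]
  g <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(nrow(co2), name = co2$id)
  if (nrow(cn2))
    g <- igraph::add_edges(g, rbind(match(cn2$source, co2$id),
                                    match(cn2$target, co2$id)))
  comp <- igraph::components(g)
  reasons <- character()
  if (comp$no != spec$expected_components)
    reasons <- c(reasons, sprintf("expected %d components, found %d",
                                  spec$expected_components, comp$no))
  if (any(comp$csize < spec$min_component_size))
    reasons <- c(reasons, "component below minimum size")
  comp_name <- sprintf("component_%d", seq_len(comp$no))
  if (!is.null(spec$anchors)) {
    anchor_comp <- integer(length(spec$anchors))
    for (i in seq_along(spec$anchors)) {
      id <- tryCatch(resolve_text(x, spec$anchors[[i]]), camnet_slice_error = function(e) NA_character_)
      anchor_comp[i] <- if (is.na(id) || !id %in% co2$id) NA_integer_ else
        comp$membership[match(id, co2$id)]
    }
    if (anyNA(anchor_comp)) {
      reasons <- c(reasons, "anchor concept missing from sliced CAM")
    } else if (anyDuplicated(anchor_comp)) {
      reasons <- c(reasons, "two anchors share a component")
    } else {
      comp_name[anchor_comp] <- names(spec$anchors)
    }
  }
  sub_cams <- lapply(seq_len(comp$no), function(kk) {
    ids <- co2$id[comp$membership == kk]
    cam(cam_id = paste0(x$cam_id, "_", comp_name[kk]),
        participant_id = x$participant_id, topic = x$topic,
        concepts = co2[co2$id %in% ids, ],
        connectors = cn2[cn2$source %in% ids & cn2$target %in% ids, ])
  })
  names(sub_cams) <- comp_name
  structure(list(verdict = if (length(reasons)) "FAIL" else "PASS",
                 n_components = as.integer(comp$no), sub_cams = sub_cams,
                 reasons = reasons), class = "cam_slice")
}

#' Compare named components across participants
#'
#' After slicing every participant's CAM with the same spec, compares two
#' named components within subjects: per-component descriptives (mean
#' valence, node count, density) and a paired t test on the per-participant
#' component mean valences, with effect size `d_z = mean(diff) / sd(diff)`.
#' Participants lacking either component are excluded with a warning; a
#' zero-variance difference yields an undefined (`NA`) t statistic.
#'
#' @param slices Named list (participant -> `cam_slice`).
#' @param component_a,component_b The two component names to compare.
#' @param ambivalent_policy Policy for mean valences.
#' @return A list: `per_participant` (tibble), `summary` (tibble per
#'   component), `t` (statistic), `df`, `p`, `effect_size`, `n_pairs`.
#' @export
component_comparison <- function(slices, component_a, component_b,
                                 ambivalent_policy = "as_zero") {
  stopifnot(length(slices) >= 1L, !is.null(names(slices)))
  rows <- list()
  for (pid in names(slices)) {
    sl <- slices[[pid]]
    if (!all(c(component_a, component_b) %in% names(sl$sub_cams))) {
      warning(sprintf("participant %s lacks both components; excluded", pid))
      next
    }
    for (comp in c(component_a, component_b)) {
      sub <- sl$sub_cams[[comp]]
      v <- numeric_valence(sub$concepts$valence, sub$concepts$ambivalent,
                           ambivalent_policy)
      n <- nrow(sub$concepts)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant = pid, component = comp,
        mean_valence = mean(v, na.rm = TRUE), n_nodes = n,
        density = if (n > 1L) nrow(sub$connectors) / (n * (n - 1) / 2) else NA_real_)
    }
  }
  per <- dplyr::bind_rows(rows)
  if (!nrow(per))
    stop_camnet("no participant contributes both components", "camnet_slice_error")
  summ <- per |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(mean_valence = mean(.data$mean_valence),
                     mean_n_nodes = mean(.data$n_nodes),
                     mean_density = mean(.data$density, na.rm = TRUE),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(per[, c("participant", "component", "mean_valence")],
                             names_from = "component", values_from = "mean_valence")
  d <- wide[[component_a]] - wide[[component_b]]
  n <- length(d)
  if (n < 2L || sd(d) == 0) {
    tt <- list(t = NA_real_, df = n - 1L, p = NA_real_,
               effect_size = NA_real_)
  } else {
    ht <- t.test(wide[[component_a]], wide[[component_b]], paired = TRUE)
    tt <- list(t = unname(ht$statistic), df = unname(ht$parameter),
               p = ht$p.value, effect_size = mean(d) / sd(d))
  }
  c(list(per_participant = per, summary = summ, n_pairs = n), tt)
}
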