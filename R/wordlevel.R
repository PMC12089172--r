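#' Word list with per-concept summary statistics
#'
#' One row per unique concept text pooled over all CAMs, with occurrence
#' count, mean/SD valence and mean/SD degree. Can operate on the raw drawn
#' texts or the summarized texts, optionally splitting summarized words by
#' valence class (e.g. `Cost_positive` vs `Cost_negative`).
#'
#' @param cams A `cam_set` (summarized or raw).
#' @param use_summarized Use the current (possibly summarized) `text` field
#'   (`TRUE`, default) or the preserved `raw_text` (`FALSE`).
#' @param split_by_valence Append the valence class to each text before
#'   tallying.
#' @param ambivalent_policy Policy for numeric valences.
#' @return A tibble (`text`, `n_total`, `mean_valence`, `sd_valence`,
#'   `mean_degree`, `sd_degree`), sorted by `n_total` desc then `text`; SDs
#'   are `NA` when `n_total = 1`.
#' @export
word_list <- function(cams, use_summarized = TRUE, split_by_valence = FALSE,
                      ambivalent_policy = "as_zero") {
  stopifnot(inherits(cams, "cam_set"))
  rows <- dplyr::bind_rows(lapply(cams$cams, function(cm) {
    co <- cm$concepts
    deg <- igraph::degree(cam_igraph(cm))
    txt <- if (use_summarized || !"raw_text" %in% names(co)) co$text else co$raw_text
    txt <- normalize_text(txt)
    if (split_by_valence)
      txt <- paste0(txt, "_", valence_class(co$valence, co$ambivalent))
    tibble::tibble(text = txt,
                   valence = numeric_valence(co$valence, co$ambivalent,
                                             ambivalent_policy),
                   degree = unname(deg[co$id]))
  }))
  out <- rows |>
    dplyr::group_by(.data$text) |>
    dplyr::summarise(n_total = dplyr::n(),
                     mean_valence = mean(.data$valence, na.rm = TRUE),
                     sd_valence = sd(.data$valence, na.rm = TRUE),
                     mean_degree = mean(.data$degree),
                     sd_degree = sd(.data$degree), .groups = "drop")
  out$sd_valence[out$n_total == 1L] <- NA_real_
  out$sd_degree[out$n_total == 1L] <- NA_real_
  out[order(-out$n_total, out$text), ]
}

#' Per-CAM concept frequencies split by valence class
#'
#' For every CAM and every unique (normalized) concept text in the set:
#' total count `N` and counts per valence class. Absent concepts get explicit
#' zero rows so the output forms a complete CAM x concept grid.
#'
#' @param cams A `cam_set`.
#' @return A tibble (`cam_id`, `text`, `N`, `N_positive`, `N_negative`,
#'   `N_neutral`, `N_ambivalent`) with `N` equal to the sum of the four
#'   classes.
#' @export
per_cam_frequencies <- function(cams) {
  stopifnot(inherits(cams, "cam_set"))
  tab <- concept_table(cams)
  tab$text <- normalize_text(tab$text)
  tab$class <- valence_class(tab$valence, tab$ambivalent)
  counts <- tab |>
    dplyr::group_by(.data$cam_id, .data$text, .data$class) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
  grid <- tidyr::expand_grid(cam_id = vapply(cams$cams, `[[`, character(1), "cam_id"),
                             text = sort(unique(tab$text)),
                             class = c("positive", "negative", "neutral", "ambivalent"))
  full <- dplyr::left_join(grid, counts, by = c("cam_id", "text", "class"))
  full$n[is.na(full$n)] <- 0L
  wide <- tidyr::pivot_wider(full, names_from = "class", values_from = "n",
                             names_prefix = "N_")
  wide$N <- wide$N_positive + wide$N_negative + wide$N_neutral + wide$N_ambivalent
  wide[, c("cam_id", "text", "N", "N_positive", "N_negative", "N_neutral", "N_ambivalent")]
}

#' Composition of each superordinate category
#'
#' For every category of a summary map: which raw texts were summarized under
#' it, how often each occurs in the data set, and its share of the category.
#' This is the data behind per-category pie charts / barplots; rendering is
#' left to the caller.
#'
#' @param cams A `cam_set` (raw texts are taken from `raw_text` when present,
#'   i.e. the set may already be summarized).
#' @param map A non-empty `summary_map`.
#' @return A tibble (`category`, `raw_text`, `n`, `share`); shares sum to 1
#'   within each category present in the data.
#' @export
category_composition <- function(cams, map) {
  stopifnot(inherits(cams, "cam_set"), inherits(map, "summary_map"))
  if (!nrow(map$entries)) stop_camnet("summary map is empty", "camnet_map_error")
  tab <- concept_table(cams)
  raw <- normalize_text(if ("raw_text" %in% names(tab)) tab$raw_text else tab$text)
  lut <- setNames(map$entries$category, map$entries$raw_text)
  hit <- raw %in% names(lut)
  df <- tibble::tibble(category = unname(lut[raw[hit]]), raw_text = raw[hit])
  out <- df |>
    dplyr::group_by(.data$category, .data$raw_text) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(share = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  out[order(out$category, -out$n, out$raw_text), ]
}
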