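#' Build a descriptive report bundle
#'
#' Dataset descriptives (CAM count, concepts and connectors per CAM,
#' valence-class shares), summarization statistics (category count, coverage,
#' top categories) and optional protocol usage statistics. All numbers are
#' recomputed from the inputs at call time.
#'
#' @param cams A `cam_set`.
#' @param map Optional `summary_map` (coverage is 0 without one).
#' @param protocol Optional `cam_protocol`.
#' @return A list of class `cam_report`.
#' @export
build_report <- function(cams, map = NULL, protocol = NULL) {
  stopifnot(inherits(cams, "cam_set"), length(cams$cams) >= 1L)
  n_concepts <- vapply(cams$cams, function(cm) nrow(cm$concepts), integer(1))
  n_connectors <- vapply(cams$cams, function(cm) nrow(cm$connectors), integer(1))
  tab <- concept_table(cams)
  cls <- valence_class(tab$valence, tab$ambivalent)
  shares <- vapply(c("positive", "negative", "neutral", "ambivalent"),
                   function(k) mean(cls == k), numeric(1))
  total <- nrow(tab)
  summarization <- if (is.null(map)) {
    list(n_categories = 0L, coverage = 0, top_categories = tibble::tibble(
      category = character(), n = integer()))
  } else {
    raw <- normalize_text(if ("raw_text" %in% names(tab)) tab$raw_text else tab$text)
    mapped <- raw %in% map$entries$raw_text
    comp <- if (any(mapped)) {
      lut <- setNames(map$entries$category, map$entries$raw_text)
      tt <- sort(table(unname(lut[raw[mapped]])), decreasing = TRUE)
      tibble::tibble(category = names(tt), n = as.integer(tt))
    } else tibble::tibble(category = character(), n = integer())
    list(n_categories = length(unique(map$entries$category)),
         coverage = mean(mapped), top_categories = head(comp, 10L))
  }
  structure(list(
    n_cams = length(cams$cams),
    concepts_per_cam = list(mean = mean(n_concepts),
                            sd = if (length(n_concepts) > 1L) sd(n_concepts) else NA_real_),
    connectors_per_cam = list(mean = mean(n_connectors),
                              sd = if (length(n_connectors) > 1L) sd(n_connectors) else NA_real_),
    n_concepts_total = total,
    valence_shares = shares,
    summarization = summarization,
    protocol = if (is.null(protocol)) NULL else protocol_stats(protocol)),
    class = "cam_report")
}

fmt <- function(x, digits = 2) {
  ifelse(is.na(x), "--", formatC(x, format = "f", digits = digits))
}

#' Render a report bundle as markdown
#'
#' Pure function: the same bundle always renders to the same bytes. Uses
#' APA-style M / SD / N notation in plain markdown tables.
#'
#' @param report A `cam_report` from [build_report()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "cam_report"))
  s <- report
  lines <- c(
    "# CAM dataset report", "",
    "## Dataset descriptives", "",
    sprintf("- CAMs: *N* = %d", s$n_cams),
    sprintf("- Concepts per CAM: *M* = %s, *SD* = %s",
            fmt(s$concepts_per_cam$mean), fmt(s$concepts_per_cam$sd)),
    sprintf("- Connectors per CAM: *M* = %s, *SD* = %s",
            fmt(s$connectors_per_cam$mean), fmt(s$connectors_per_cam$sd)),
    sprintf("- Concepts total: %d", s$n_concepts_total), "",
    "| Valence class | Share |", "|---|---|",
    sprintf("| %s | %s |", names(s$valence_shares), fmt(s$valence_shares, 3)),
    "",
    "## Summarization", "",
    sprintf("- Categories: %d", s$summarization$n_categories),
    sprintf("- Coverage: %s of concepts mapped", fmt(s$summarization$coverage, 3)))
  if (nrow(s$summarization$top_categories)) {
    lines <- c(lines, "", "| Category | n |", "|---|---|",
               sprintf("| %s | %d |", s$summarization$top_categories$category,
                       s$summarization$top_categories$n))
  }
  if (!is.null(s$protocol)) {
    lines <- c(lines, "", "## Protocol", "",
               sprintf("- Entries: %d", attr(s$protocol, "n_entries")),
               "", "| Operation | n |", "|---|---|",
               sprintf("| %s | %d |", s$protocol$operation, s$protocol$n))
  }
  lines
}

#' @export
print.cam_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
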