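#' Construct a CAM object
#'
#' A cognitive-affective map (CAM) is one participant's belief network: a set
#' of concepts, each carrying free text, an optional comment, an affective
#' valence (integer -3..+3 or the distinct state *ambivalent*) and a drawing
#' position, together with connectors of signed strength (-3..-1, +1..+3;
#' positive = supporting, negative = opposing) that may be directed.
#'
#' @param cam_id Unique identifier of the CAM.
#' @param concepts A data frame with columns `id`, `text`, and optionally
#'   `comment`, `valence` (integer, `NA` allowed only when `ambivalent` is
#'   `TRUE`), `ambivalent` (logical), `x`, `y`, `predefined`, `raw_text`.
#' @param connectors A data frame with columns `id`, `source`, `target`,
#'   `strength`, `directed`, or `NULL` for a connector-free CAM.
#' @param participant_id Participant identifier (may be empty).
#' @param topic Optional study topic string.
#' @param drawn_at Optional timestamp string; stored, never analyzed.
#'
#' @return An object of class `cam`.
#' @export
cam <- function(cam_id, concepts, connectors = NULL, participant_id = "",
                topic = NULL, drawn_at = NULL) {
  concepts <- as_concept_table(concepts)
  connectors <- as_connector_table(connectors)
  obj <- structure(
    list(cam_id = as.character(cam_id),
         participant_id = as.character(participant_id),
         topic = if (is.null(topic)) NULL else as.character(topic),
         drawn_at = if (is.null(drawn_at)) NULL else as.character(drawn_at),
         concepts = concepts, connectors = connectors),
    class = "cam")
  validate_cam(obj)
  obj
}

as_concept_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("id", "text") %in% names(df)))
    stop_camnet("concept table needs at least columns 'id' and 'text'", "camnet_parse_error")
  n <- nrow(df)
  tab <- tibble::tibble(
    id = as.character(df$id),
    text = as.character(df$text),
    comment = if ("comment" %in% names(df)) as.character(df$comment) else rep("", n),
    valence = if ("valence" %in% names(df)) as.integer(df$valence) else rep(0L, n),
    ambivalent = if ("ambivalent" %in% names(df)) as.logical(df$ambivalent) else rep(FALSE, n),
    x = if ("x" %in% names(df)) as.numeric(df$x) else rep(0, n),
    y = if ("y" %in% names(df)) as.numeric(df$y) else rep(0, n),
    predefined = if ("predefined" %in% names(df)) as.logical(df$predefined) else rep(FALSE, n))
  if ("raw_text" %in% names(df)) tab$raw_text <- as.character(df$raw_text)
  tab$comment[is.na(tab$comment)] <- ""
  tab$valence[tab$ambivalent] <- NA_integer_
  tab
}

as_connector_table <- function(df) {
  if (is.null(df) || (is.data.frame(df) && nrow(df) == 0)) {
    return(tibble::tibble(id = character(), source = character(),
                          target = character(), strength = integer(),
                          directed = logical()))
  }
  df <- tibble::as_tibble(df)
  need <- c("id", "source", "target", "strength")
  if (!all(need %in% names(df)))
    stop_camnet("connector table needs columns id, source, target, strength", "camnet_parse_error")
  tibble::tibble(
    id = as.character(df$id),
    source = as.character(df$source),
    target = as.character(df$target),
    strength = as.integer(df$strength),
    directed = if ("directed" %in% names(df)) as.logical(df$directed) else rep(FALSE, nrow(df)))
}

#' Check the structural invariants of a CAM
#'
#' Verifies concept/connector id uniqueness, valence range, endpoint
#' resolution, absence of self-loops and of parallel connectors (CAMs are
#' simple graphs), and non-zero connector strengths in -3..+3.
#'
#' @param x A `cam` object.
#' @return `x`, invisibly; errors of class `camnet_integrity_error` otherwise.
#' @export
validate_cam <- function(x) {
  co <- x$concepts; cn <- x$connectors
  if (anyDuplicated(co$id))
    stop_camnet(paste("duplicate concept ids:",
                      paste(unique(co$id[duplicated(co$id)]), collapse = ", ")),
                "camnet_integrity_error")
  if (anyDuplicated(cn$id))
    stop_camnet("duplicate connector ids", "camnet_integrity_error")
  bad_val <- !co$ambivalent & (is.na(co$valence) | co$valence < -3L | co$valence > 3L)
  if (any(bad_val))
    stop_camnet(paste("valence outside -3..3 for concept(s):",
                      paste(co$id[bad_val], collapse = ", ")), "camnet_integrity_error")
  empty <- !co$predefined & !nzchar(trimws(co$text))
  if (any(empty))
    stop_camnet(paste("empty text for non-predefined concept(s):",
                      paste(co$id[empty], collapse = ", ")), "camnet_integrity_error")
  if (nrow(cn)) {
    dangling <- setdiff(c(cn$source, cn$target), co$id)
    if (length(dangling))
      stop_camnet(paste("connector endpoint(s) not found:",
                        paste(dangling, collapse = ", ")), "camnet_integrity_error")
    if (any(cn$source == cn$target))
      stop_camnet("self-loop connector(s) not allowed", "camnet_integrity_error")
    if (any(is.na(cn$strength) | cn$strength == 0L | abs(cn$strength) > 3L))
      stop_camnet("connector strength must be in -3..-1 or 1..3", "camnet_integrity_error")
    key <- pair_key(cn$source, cn$target)
    if (anyDuplicated(key))
      stop_camnet("multiple connectors between the same concept pair", "camnet_integrity_error")
  }
  invisible(x)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' @export
print.cam <- function(x, ...) {
  cat(sprintf("<cam> %s (participant %s): %d concepts, %d connectors\n",
              x$cam_id, x$participant_id, nrow(x$concepts), nrow(x$connectors)))
  invisible(x)
}

#' Bundle CAMs into an ordered set
#'
#' @param cams A list of `cam` objects (or a single `cam`).
#' @param provenance Optional character vector of source file paths.
#' @return An object of class `cam_set`.
#' @export
cam_set <- function(cams, provenance = character()) {
  if (inherits(cams, "cam")) cams <- list(cams)
  stopifnot(all(vapply(cams, inherits, logical(1), "cam")))
  ids <- vapply(cams, `[[`, character(1), "cam_id")
  if (anyDuplicated(ids))
    stop_camnet(paste("duplicate cam_id in set:",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                "camnet_integrity_error")
  structure(list(cams = setNames(cams, ids), provenance = provenance),
            class = "cam_set")
}

#' @export
print.cam_set <- function(x, ...) {
  cat(sprintf("<cam_set> %d CAMs, %d concepts total\n", length(x$cams),
              sum(vapply(x$cams, function(c) nrow(c$concepts), integer(1)))))
  invisible(x)
}

#' @export
length.cam_set <- function(x) length(x$cams)

#' All concepts of a CAM set as one table
#'
#' @param cams A `cam_set`.
#' @return A tibble of all concept rows with a leading `cam_id` column.
#' @export
concept_table <- function(cams) {
  stopifnot(inherits(cams, "cam_set"))
  dplyr::bind_rows(lapply(cams$cams, function(cm) {
    co <- cm$concepts
    if (!"raw_text" %in% names(co)) co$raw_text <- co$text
    dplyr::bind_cols(tibble::tibble(cam_id = rep(cm$cam_id, nrow(co))), co)
  }))
}

#' Parse a CAM from its JSON document
#'
#' Reads the canonical CAM JSON schema: an object with `cam_id`,
#' `participant_id`, optional `topic`, a `concepts` array
#' (`id`,`text`,`comment`,`valence`,`position:{x,y}`,`predefined`) and a
#' `connectors` array (`id`,`source`,`target`,`strength`,`directed`).
#' `valence` is an integer -3..3 or the string `"ambivalent"`. A legacy numeric
#' ambivalent code (as used by older Valence-style exports) is mapped to the
#' ambivalent marker.
#'
#' @param raw A JSON string, a file path, or an already-parsed list.
#' @param ambivalent_code Numeric legacy code to interpret as ambivalent
#'   (default 10).
#' @return A `cam` object.
#' @export
parse_cam <- function(raw, ambivalent_code = 10) {
  if (is.character(raw) && length(raw) == 1L) {
    doc <- jsonlite::fromJSON(raw, simplifyVector = FALSE)
  } else if (is.list(raw)) {
    doc <- raw
  } else stop_camnet("raw must be a JSON string, a path, or a list", "camnet_parse_error")
  if (is.null(doc$cam_id)) stop_camnet("missing field: cam_id", "camnet_parse_error")
  cps <- doc$concepts %||% list()
  cns <- doc$connectors %||% list()
  concepts <- dplyr::bind_rows(lapply(cps, function(p) {
    if (is.null(p$id)) stop_camnet("concept missing field: id", "camnet_parse_error")
    if (is.null(p$text)) stop_camnet(paste0("concept ", p$id, " missing field: text"), "camnet_parse_error")
    v <- p$valence
    amb <- FALSE
    if (is.null(v)) stop_camnet(paste0("concept ", p$id, " missing field: valence"), "camnet_parse_error")
    if (identical(v, "ambivalent") || (is.numeric(v) && v == ambivalent_code)) {
      amb <- TRUE; v <- NA_integer_
    } else if (is.numeric(v) && v >= -3 && v <= 3 && v == round(v)) {
      v <- as.integer(v)
    } else stop_camnet(paste0("concept ", p$id, ": invalid valence"), "camnet_parse_error")
    tibble::tibble(id = as.character(p$id), text = as.character(p$text),
                   comment = as.character(p$comment %||% ""),
                   valence = v, ambivalent = amb,
                   x = as.numeric(p$position$x %||% 0),
                   y = as.numeric(p$position$y %||% 0),
                   predefined = isTRUE(p$predefined),
                   raw_text = as.character(p$raw_text %||% NA_character_))
  }))
  if (nrow(concepts) && all(is.na(concepts$raw_text))) concepts$raw_text <- NULL
  connectors <- dplyr::bind_rows(lapply(cns, function(e) {
    for (f in c("id", "source", "target", "strength"))
      if (is.null(e[[f]])) stop_camnet(paste("connector missing field:", f), "camnet_parse_error")
    tibble::tibble(id = as.character(e$id), source = as.character(e$source),
                   target = as.character(e$target),
                   strength = as.integer(e$strength),
                   directed = isTRUE(e$directed))
  }))
  cam(cam_id = doc$cam_id, participant_id = doc$participant_id %||% "",
      topic = doc$topic, drawn_at = doc$drawn_at,
      concepts = concepts, connectors = connectors)
}

#' Serialize a CAM to canonical JSON
#'
#' The canonical form has alphabetically sorted keys and concepts/connectors
#' sorted by id, so structurally equal CAMs serialize to byte-identical
#' documents. Ambivalent valences serialize as the string `"ambivalent"`.
#'
#' @param x A `cam` object.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
write_cam <- function(x, path = NULL) {
  validate_cam(x)
  co <- x$concepts[order(x$concepts$id), ]
  cn <- x$connectors[order(x$connectors$id), ]
  clist <- lapply(seq_len(nrow(co)), function(i) {
    r <- co[i, ]
    out <- list(comment = jsonlite::unbox(r$comment),
                id = jsonlite::unbox(r$id),
                position = list(x = jsonlite::unbox(r$x), y = jsonlite::unbox(r$y)),
                predefined = jsonlite::unbox(r$predefined),
                text = jsonlite::unbox(r$text),
                valence = jsonlite::unbox(if (r$ambivalent) "ambivalent" else r$valence))
    if ("raw_text" %in% names(co) && !is.na(r$raw_text))
      out$raw_text <- jsonlite::unbox(r$raw_text)
    out[order(names(out))]
  })
  elist <- lapply(seq_len(nrow(cn)), function(i) {
    r <- cn[i, ]
    list(directed = jsonlite::unbox(r$directed), id = jsonlite::unbox(r$id),
         source = jsonlite::unbox(r$source), strength = jsonlite::unbox(r$strength),
         target = jsonlite::unbox(r$target))
  })
  doc <- list(cam_id = jsonlite::unbox(x$cam_id),
              concepts = clist, connectors = elist,
              participant_id = jsonlite::unbox(x$participant_id))
  if (!is.null(x$topic)) doc$topic <- jsonlite::unbox(x$topic)
  if (!is.null(x$drawn_at)) doc$drawn_at <- jsonlite::unbox(x$drawn_at)
  doc <- doc[order(names(doc))]
  js <- jsonlite::toJSON(doc, digits = NA, null = "null", pretty = FALSE)
  js <- as.character(js)
  if (!is.null(path)) {
    writeLines(js, path, useBytes = TRUE)
    return(invisible(js))
  }
  js
}

#' Read several CAM JSON files into a set
#'
#' @param paths Character vector of file paths.
#' @param ambivalent_code Legacy ambivalent code passed to [parse_cam()].
#' @return A `cam_set` with `provenance` recording the paths.
#' @export
read_cam_set <- function(paths, ambivalent_code = 10) {
  for (p in paths) if (!file.exists(p))
    stop_camnet(paste("file not found:", p), "camnet_io_error")
  cam_set(lapply(paths, parse_cam, ambivalent_code = ambivalent_code),
          provenance = paths)
}

#' Write every CAM of a set to a directory
#'
#' @param cams A `cam_set`.
#' @param dir Output directory (created if missing).
#' @return The written file paths, invisibly.
#' @export
write_cam_set <- function(cams, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cams$cams, function(cm) {
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", cm$cam_id), ".json"))
    write_cam(cm, p)
    p
  }, character(1))
  invisible(unname(paths))
}

#' Study configuration (data-collection parameters)
#'
#' The parameters a researcher sets for a drawing study, used here to validate
#' collected CAMs: the minimum number of concepts, per-concept word and
#' character limits, and whether ambivalent concepts, directed arrows and
#' opposing (negative) connections were enabled.
#'
#' @param min_num_nodes Integer 1..50.
#' @param max_num_words Integer 1..5 (whitespace-tokenized words per concept).
#' @param max_length_chars Integer 30..300 (raw character count per concept).
#' @param enable_ambivalent,enable_arrows,bidirectional_default,only_straight_con
#'   Logical switches mirroring the study setup.
#' @return An object of class `study_config`.
#' @export
study_config <- function(min_num_nodes = 1L, max_num_words = 5L,
                         max_length_chars = 300L, enable_ambivalent = TRUE,
                         enable_arrows = TRUE, bidirectional_default = TRUE,
                         only_straight_con = FALSE) {
  chk <- function(v, lo, hi, nm) {
    v <- as.integer(v)
    if (is.na(v) || v < lo || v > hi)
      stop_camnet(sprintf("%s must be in %d..%d", nm, lo, hi), "camnet_config_error")
    v
  }
  structure(list(
    min_num_nodes = chk(min_num_nodes, 1L, 50L, "min_num_nodes"),
    max_num_words = chk(max_num_words, 1L, 5L, "max_num_words"),
    max_length_chars = chk(max_length_chars, 30L, 300L, "max_length_chars"),
    enable_ambivalent = isTRUE(enable_ambivalent),
    enable_arrows = isTRUE(enable_arrows),
    bidirectional_default = isTRUE(bidirectional_default),
    only_straight_con = isTRUE(only_straight_con)), class = "study_config")
}

#' Validate a CAM against a study configuration
#'
#' Applies the save-time rules of the data-collection setup: enough concepts
#' drawn, no disconnected concepts, word/character limits per concept, and the
#' feature switches (ambivalence, arrows, opposing connections). Violations are
#' returned as data, not raised as errors.
#'
#' @param x A `cam`.
#' @param cfg A [study_config()].
#' @return A tibble with columns `rule` (one of `TOO_FEW_NODES`,
#'   `DISCONNECTED_CONCEPT`, `TOO_MANY_WORDS`, `TOO_MANY_CHARS`,
#'   `AMBIVALENT_DISABLED`, `ARROW_DISABLED`, `OPPOSING_DISABLED`) and
#'   `element` (offending concept/connector id, `""` for CAM-level rules).
#'   Zero rows iff the CAM is compliant.
#' @export
validate_against_config <- function(x, cfg) {
  stopifnot(inherits(x, "cam"), inherits(cfg, "study_config"))
  co <- x$concepts; cn <- x$connectors
  out <- list()
  add <- function(rule, element = "") {
    out[[length(out) + 1L]] <<- tibble::tibble(rule = rule, element = element)
  }
  if (nrow(co) < cfg$min_num_nodes) add("TOO_FEW_NODES")
  if (nrow(co) > 1L) {
    connected <- unique(c(cn$source, cn$target))
    for (id in sort(setdiff(co$id, connected))) add("DISCONNECTED_CONCEPT", id)
  }
  too_many <- count_words(co$text) > cfg$max_num_words
  for (id in co$id[too_many]) add("TOO_MANY_WORDS", id)
  too_long <- nchar(co$text) > cfg$max_length_chars
  for (id in co$id[too_long]) add("TOO_MANY_CHARS", id)
  if (!cfg$enable_ambivalent) for (id in co$id[co$ambivalent]) add("AMBIVALENT_DISABLED", id)
  if (!cfg$enable_arrows && nrow(cn)) for (id in cn$id[cn$directed]) add("ARROW_DISABLED", id)
  if (cfg$only_straight_con && nrow(cn)) for (id in cn$id[cn$strength < 0L]) add("OPPOSING_DISABLED", id)
  if (!length(out)) return(tibble::tibble(rule = character(), element = character()))
  dplyr::bind_rows(out)
}

#' Edge list of a CAM
#'
#' @param x A `cam`.
#' @return A tibble (`source`, `target`, `strength`, `directed`), one row per
#'   connector, ordered by connector id; lossless with respect to connectors.
#' @export
to_edge_list <- function(x) {
  stopifnot(inherits(x, "cam"))
  cn <- x$connectors[order(x$connectors$id), ]
  tibble::tibble(source = cn$source, target = cn$target,
                 strength = cn$strength, directed = cn$directed)
}

#' Rebuild a CAM from a concept table and an edge list
#'
#' Inverse of [to_edge_list()] plus the concept table: produces a CAM
#' isomorphic to the original (connector ids are regenerated).
#'
#' @param concepts Concept table (`id`,`text`,`comment`,`valence`,
#'   `ambivalent`,`x`,`y`,`predefined`).
#' @param edges Edge list as returned by [to_edge_list()].
#' @param cam_id,participant_id Identifiers for the rebuilt CAM.
#' @return A `cam`.
#' @export
cam_from_tables <- function(concepts, edges, cam_id, participant_id = "") {
  edges <- tibble::as_tibble(edges)
  cn <- if (nrow(edges)) tibble::tibble(
    id = sprintf("e%d", seq_len(nrow(edges))),
    source = as.character(edges$source), target = as.character(edges$target),
    strength = as.integer(edges$strength),
    directed = as.logical(edges$directed %||% FALSE)) else NULL
  cam(cam_id = cam_id, participant_id = participant_id,
      concepts = concepts, connectors = cn)
}

#' Undirected igraph projection of a CAM
#'
#' All distance/degree computations ignore arrow direction; vertices carry
#' `text`, `valence` (numeric, ambivalent under the given policy) and
#' `ambivalent` attributes, edges carry `strength` and `weight = |strength|`.
#'
#' @param x A `cam`.
#' @param ambivalent_policy Passed to [numeric_valence()].
#' @return An `igraph` graph.
#' @export
cam_igraph <- function(x, ambivalent_policy = "as_zero") {
  stopifnot(inherits(x, "cam"))
  co <- x$concepts
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(co), name = co$id, text = co$text,
                            valence = numeric_valence(co$valence, co$ambivalent,
                                                      ambivalent_policy),
                            ambivalent = co$ambivalent)
  cn <- x$connectors
  if (nrow(cn)) {
    g <- igraph::add_edges(g, rbind(match(cn$source, co$id), match(cn$target, co$id)),
                           strength = cn$strength, weight = abs(cn$strength))
  }
  g
}

#' Export a CAM as GraphML
#'
#' @param x A `cam`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cam_graphml <- function(x, path) {
  igraph::write_graph(cam_igraph(x), path, format = "graphml")
  invisible(path)
}

# structural equality used by round-trip tests and protocol digests
cam_equal <- function(a, b) {
  norm <- function(cm) {
    co <- cm$concepts[order(cm$concepts$id), ]
    if (!"raw_text" %in% names(co)) co$raw_text <- co$text
    cn <- cm$connectors[order(cm$connectors$id), ]
    list(cm$cam_id, cm$participant_id, cm$topic %||% "", co, cn)
  }
  isTRUE(all.equal(norm(a), norm(b)))
}
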