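#' Optimal string alignment distance
#'
#' Restricted Damerau-Levenshtein edit distance: insertions, deletions,
#' substitutions and transpositions of adjacent characters, with the
#' restriction that no substring is edited more than once. This is the
#' distance used to flag likely spelling variants among drawn concepts, e.g.
#' `osa_distance("dreams", "dreasm") == 1` (one adjacent transposition).
#'
#' Unlike the unrestricted Damerau-Levenshtein distance, OSA can violate the
#' triangle inequality (e.g. "ca" vs "abc" is 3 under OSA, 2 unrestricted).
#'
#' @param s,t Character strings (empty strings allowed).
#' @return Non-negative integer distance; 0 iff the strings are equal.
#' @export
osa_distance <- function(s, t) {
  stopifnot(is_string(s) || s == "", is_string(t) || t == "")
  a <- utf8ToInt(s); b <- utf8ToInt(t)
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  # three rolling rows of the DP table
  prev2 <- integer(m + 1L)
  prev <- 0L:m
  for (i in 1L:n) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in 1L:m) {
      cost <- if (a[i] == b[j]) 0L else 1L
      d <- min(prev[j + 1L] + 1L,      # deletion
               cur[j] + 1L,            # insertion
               prev[j] + cost)         # substitution / match
      if (i > 1L && j > 1L && a[i] == b[j - 1L] && a[i - 1L] == b[j])
        d <- min(d, prev2[j - 1L] + 1L)  # adjacent transposition
      cur[j + 1L] <- d
    }
    prev2 <- prev
    prev <- cur
  }
  prev[m + 1L]
}

# connected components over an index-pair link list; returns membership vector
component_groups <- function(n, links) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(links)) for (k in seq_len(nrow(links))) {
    ri <- find(links[k, 1L]); rj <- find(links[k, 2L])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, integer(1))
}

# assemble groups (>= min_size members) into the standard suggestion tibble,
# ordered by group size desc then lexicographic representative
build_suggestions <- function(texts, membership, source, score_fun, min_size = 2L) {
  groups <- split(texts, membership)
  groups <- Filter(function(g) length(g) >= min_size, groups)
  if (!length(groups))
    return(tibble::tibble(group = integer(), member = character(),
                          source = character(), score = numeric()))
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, `[[`, character(1), 1L))
  groups <- groups[ord]
  dplyr::bind_rows(lapply(seq_along(groups), function(i) {
    tibble::tibble(group = i, member = groups[[i]], source = source,
                   score = score_fun(groups[[i]]))
  }))
}

#' Suggest concept groups by approximate string matching
#'
#' Computes OSA distances between all unique (normalized) concept texts and
#' links pairs with distance at most `max_dist`; suggestion groups are the
#' connected components of that link graph (single-linkage closure), so chains
#' of near-identical spellings end up in one group.
#'
#' @param texts Character vector of concept texts.
#' @param max_dist Maximum OSA distance linking two texts (default 1).
#' @return A tibble (`group`, `member`, `source = "distance"`, `score`), where
#'   `score` is the largest pairwise OSA distance inside the group; groups are
#'   ordered by size (desc) then by lexicographic representative.
#' @export
suggest_by_distance <- function(texts, max_dist = 1L) {
  stopifnot(max_dist >= 1L)
  u <- sort(unique(normalize_text(texts)))
  u <- u[nzchar(u)]
  n <- length(u)
  if (n < 2L) return(build_suggestions(u, seq_len(n), "distance", function(g) 0))
  links <- matrix(integer(), 0L, 2L)
  dmat <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- osa_distance(u[i], u[j])
    dmat[i, j] <- dmat[j, i] <- d
    if (d <= max_dist) links <- rbind(links, c(i, j))
  }
  memb <- component_groups(n, links)
  score_fun <- function(g) {
    idx <- match(g, u)
    max(dmat[idx, idx, drop = FALSE])
  }
  build_suggestions(u, memb, "distance", score_fun)
}

#' Search concept texts with a regular expression
#'
#' Matching is case-insensitive by default and supports POSIX character
#' classes such as `[[:digit:]]` (so all concepts containing digits can be
#' found with that single class).
#'
#' @param texts Character vector of concept texts.
#' @param pattern Regular expression.
#' @param ignore_case Case-insensitive matching (default `TRUE`).
#' @return The matching texts (unique, normalized, sorted).
#' @export
search_terms <- function(texts, pattern, ignore_case = TRUE) {
  u <- sort(unique(normalize_text(texts)))
  hit <- tryCatch(suppressWarnings(grepl(pattern, u, ignore.case = ignore_case)),
                  error = function(e) stop_camnet(
                    paste("invalid pattern:", conditionMessage(e)),
                    "camnet_pattern_error"))
  u[hit]
}

#' Load a synonym dictionary
#'
#' Reads a JSON object mapping each word to an array of synonyms. The relation
#' is symmetrized at load time: if a lists b, b also lists a. A small built-in
#' English fixture ships with the package
#' (`system.file("extdata", "synonyms_en.json", package = "camnet")`);
#' real dictionaries plug in through the same format.
#'
#' @param path Path to the JSON dictionary.
#' @return A named list: word -> character vector of synonyms.
#' @export
read_synonym_dictionary <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  dict <- lapply(raw, as.character)
  names(dict) <- normalize_text(names(dict))
  dict <- lapply(dict, normalize_text)
  # symmetrize
  for (w in names(dict)) for (s in dict[[w]]) {
    dict[[s]] <- union(dict[[s]] %||% character(), w)
  }
  dict
}

#' Suggest concept groups via a synonym dictionary
#'
#' Only single-word texts participate. Each word's synonym set (including the
#' word itself) is looked up; two words are linked when their sets intersect,
#' and groups are the connected components with at least two members.
#'
#' @param texts Character vector of concept texts.
#' @param dictionary Named list word -> synonyms, e.g. from
#'   [read_synonym_dictionary()]. Missing entries mean an empty synonym set.
#' @return A tibble (`group`, `member`, `source = "synonym"`, `score` = group
#'   size).
#' @export
synonym_groups <- function(texts, dictionary) {
  u <- sort(unique(normalize_text(texts)))
  u <- u[nzchar(u) & count_words(u) == 1L]
  n <- length(u)
  if (n < 2L) return(build_suggestions(character(), integer(), "synonym", length))
  sets <- lapply(u, function(w) union(w, dictionary[[w]] %||% character()))
  links <- matrix(integer(), 0L, 2L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (length(intersect(sets[[i]], sets[[j]]))) links <- rbind(links, c(i, j))
  }
  build_suggestions(u, component_groups(n, links), "synonym", length)
}

#' Cosine similarity between two vectors
#'
#' `dot(u, v) / (|u| * |v|)`, in `[-1, 1]`: -1 for opposite, 0 for orthogonal,
#' 1 for proportional vectors.
#'
#' @param u,v Numeric vectors of equal length, both nonzero.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    stop_camnet("vectors must have equal dimension", "camnet_similarity_error")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop_camnet("cosine similarity undefined for a zero vector", "camnet_similarity_error")
  sum(u * v) / (nu * nv)
}

#' Read a word-vector table
#'
#' CSV with a `text` column followed by numeric vector components
#' (`v1`..`vd`). This is the pluggable replacement for bundled embedding
#' models: any provider that can emit such a table can drive
#' [embedding_suggestions()].
#'
#' @param path CSV file path.
#' @return A named list text -> numeric vector.
#' @export
read_vector_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"text" %in% names(df))
    stop_camnet("vector table needs a 'text' column", "camnet_io_error")
  vecs <- lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, -1, drop = TRUE]))
  setNames(vecs, normalize_text(df$text))
}

#' Suggest concept groups by word-vector similarity
#'
#' Pairs of texts whose vectors have cosine similarity at or above `threshold`
#' are linked; groups are the connected components. Texts without a vector are
#' skipped and reported.
#'
#' @param texts Character vector of concept texts.
#' @param vectors Named list text -> numeric vector (may be partial).
#' @param threshold Similarity threshold in `(-1, 1]`.
#' @return A list with `groups` (tibble `group`, `member`,
#'   `source = "embedding"`, `score` = minimum pairwise similarity inside the
#'   group) and `missing` (texts lacking vectors).
#' @export
embedding_suggestions <- function(texts, vectors, threshold) {
  stopifnot(threshold > -1, threshold <= 1)
  u <- sort(unique(normalize_text(texts)))
  u <- u[nzchar(u)]
  have <- u[u %in% names(vectors)]
  missing <- setdiff(u, have)
  n <- length(have)
  smat <- matrix(1, n, n)
  links <- matrix(integer(), 0L, 2L)
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- cosine_similarity(vectors[[have[i]]], vectors[[have[j]]])
    smat[i, j] <- smat[j, i] <- s
    # tolerance so proportional vectors pass a threshold of exactly 1
    if (s >= threshold - 1e-9) links <- rbind(links, c(i, j))
  }
  memb <- component_groups(max(n, 0L), links)
  score_fun <- function(g) {
    idx <- match(g, have)
    min(smat[idx, idx, drop = FALSE])
  }
  groups <- build_suggestions(have, memb, "embedding", score_fun)
  list(groups = groups, missing = missing)
}

#' Build a summary map
#'
#' The researcher's mapping from raw concept texts (case-folded) to
#' superordinate category labels, as produced by the five-step qualitative
#' summarization procedure. Optionally, applying the map splits categories by
#' valence sign (e.g. `Cost_positive` vs `Cost_negative`) to keep the distinct
#' meanings of identically named concepts apart.
#'
#' @param entries A data frame with columns `raw_text` and `category`, or a
#'   named character vector (names = raw texts).
#' @param split_by_valence Append `_positive` / `_negative` / `_neutral` /
#'   `_ambivalent` to the category on application.
#' @return An object of class `summary_map`.
#' @export
summary_map <- function(entries, split_by_valence = FALSE) {
  if (is.character(entries) && !is.null(names(entries))) {
    entries <- tibble::tibble(raw_text = names(entries), category = unname(entries))
  }
  entries <- tibble::as_tibble(entries)
  stopifnot(all(c("raw_text", "category") %in% names(entries)))
  entries$raw_text <- normalize_text(entries$raw_text)
  entries$category <- as.character(entries$category)
  if (any(!nzchar(entries$category)))
    stop_camnet("category labels must be non-empty", "camnet_map_error")
  if (anyDuplicated(entries$raw_text))
    stop_camnet("each raw text must map to exactly one category", "camnet_map_error")
  structure(list(entries = entries[order(entries$raw_text), ],
                 split_by_valence = isTRUE(split_by_valence)),
            class = "summary_map")
}

#' Read / write a summary map as CSV
#'
#' @param path CSV file with columns `raw_text`, `category`.
#' @param split_by_valence See [summary_map()].
#' @return [read_summary_map()] returns a `summary_map`;
#'   [write_summary_map()] returns `path` invisibly.
#' @export
read_summary_map <- function(path, split_by_valence = FALSE) {
  summary_map(read.csv(path, stringsAsFactors = FALSE), split_by_valence)
}

#' @rdname read_summary_map
#' @param map A `summary_map`.
#' @export
write_summary_map <- function(map, path) {
  write.csv(map$entries, path, row.names = FALSE)
  invisible(path)
}

valence_class <- function(valence, ambivalent) {
  ifelse(ambivalent, "ambivalent",
         ifelse(valence > 0L, "positive", ifelse(valence < 0L, "negative", "neutral")))
}

#' Apply a summary map to a CAM set
#'
#' Every concept whose normalized text appears in the map gets its text
#' replaced by the category label (suffixed by valence class when the map has
#' `split_by_valence`). The original text is preserved in the `raw_text`
#' field; valences, connectors and graph structure are never touched, so the
#' operation is idempotent.
#'
#' @param cams A `cam_set`.
#' @param map A `summary_map`.
#' @return A new `cam_set` with summarized concept texts.
#' @export
apply_summary <- function(cams, map) {
  stopifnot(inherits(cams, "cam_set"), inherits(map, "summary_map"))
  lut <- setNames(map$entries$category, map$entries$raw_text)
  out <- lapply(cams$cams, function(cm) {
    co <- cm$concepts
    if (!"raw_text" %in% names(co)) co$raw_text <- co$text
    key <- normalize_text(co$text)
    hit <- key %in% names(lut)
    if (any(hit)) {
      label <- unname(lut[key[hit]])
      if (map$split_by_valence) {
        label <- paste0(label, "_", valence_class(co$valence[hit], co$ambivalent[hit]))
      }
      co$text[hit] <- label
    }
    cm$concepts <- co
    cm
  })
  cam_set(out, provenance = cams$provenance)
}

#' Overview of not-yet-summarized concepts
#'
#' @param cams A `cam_set`.
#' @param map A `summary_map` (its entries define what counts as summarized).
#' @return A tibble (`text`, `n`) of unique unmapped normalized texts with
#'   occurrence counts, sorted by frequency desc then lexicographically.
#' @export
unsummarized_overview <- function(cams, map) {
  stopifnot(inherits(cams, "cam_set"), inherits(map, "summary_map"))
  texts <- normalize_text(concept_table(cams)$text)
  texts <- texts[!texts %in% map$entries$raw_text]
  if (!length(texts)) return(tibble::tibble(text = character(), n = integer()))
  tab <- table(texts)
  out <- tibble::tibble(text = names(tab), n = as.integer(tab))
  out[order(-out$n, out$text), ]
}
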