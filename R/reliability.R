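#' A single rater's coding of concepts into categories
#'
#' Raters assign each sampled concept text to a superordinate category using
#' their own vocabulary; only the induced partition matters for reliability,
#' not the category names.
#'
#' @param rater_id Identifier of the rater.
#' @param assignments A data frame with columns `concept`, `category`, or a
#'   named character vector (names = concepts).
#' @return An object of class `rater_coding`.
#' @export
rater_coding <- function(rater_id, assignments) {
  if (is.character(assignments) && !is.null(names(assignments))) {
    assignments <- tibble::tibble(concept = names(assignments),
                                  category = unname(assignments))
  }
  assignments <- tibble::as_tibble(assignments)
  stopifnot(all(c("concept", "category") %in% names(assignments)))
  assignments$concept <- normalize_text(assignments$concept)
  assignments$category <- as.character(assignments$category)
  if (anyDuplicated(assignments$concept))
    stop_camnet("each concept must be assigned exactly one category", "camnet_coding_error")
  structure(list(rater_id = as.character(rater_id),
                 assignments = assignments[order(assignments$concept), ]),
            class = "rater_coding")
}

#' Read a rater coding CSV
#'
#' @param path CSV with columns `concept`, `category`.
#' @param rater_id Rater identifier; defaults to the file name.
#' @return A `rater_coding`.
#' @export
read_rater_coding <- function(path, rater_id = NULL) {
  rater_coding(rater_id %||% tools::file_path_sans_ext(basename(path)),
               read.csv(path, stringsAsFactors = FALSE))
}

#' Draw a training sample of unique concepts
#'
#' For rater training, a random subset of all unique concept texts in the data
#' set is drawn (e.g. 10%), to be coded independently by every rater.
#'
#' @param cams A `cam_set`.
#' @param proportion Fraction in (0, 1]; `ceiling(proportion * n_unique)`
#'   texts are drawn without replacement.
#' @param seed Integer seed; the same seed reproduces the same sample.
#' @return Character vector of sampled unique (normalized) concept texts.
#' @export
sample_training_concepts <- function(cams, proportion, seed) {
  stopifnot(inherits(cams, "cam_set"), proportion > 0, proportion <= 1)
  u <- sort(unique(normalize_text(concept_table(cams)$text)))
  if (!length(u)) stop_camnet("CAM set contains no concepts", "camnet_coding_error")
  k <- ceiling(proportion * length(u))
  withr::with_seed(as.integer(seed), sort(sample(u, k)))
}

#' Align rater categories onto a shared label space
#'
#' Reliability must not depend on the category *names* raters invent, only on
#' whether they group the same concepts together. Alignment relabels each
#' rater's categories onto a shared integer space anchored at the rater with
#' the most categories (ties: first by rater id):
#'
#' * `exact_overlap`: a rater's category is mapped onto a reference category
#'   only when the two contain *exactly* the same concepts (a perfect match);
#'   all other categories get fresh indices. Under independent random coding
#'   no categories match, both marginals live in disjoint index spaces and
#'   kappa is exactly 0 -- this variant is strictly calibrated but
#'   conservative in the presence of noise.
#' * `max_overlap`: one-to-one assignment maximizing the *total* number of
#'   overlapping items (weighted maximum bipartite matching); unmatched
#'   categories get fresh indices. Because the alignment itself maximizes
#'   agreement, this coefficient is slightly optimistic under the null of
#'   independent coding.
#'
#' Both variants depend only on the partition structure, never on the labels.
#'
#' @param codings A list of at least two [rater_coding()] objects covering
#'   identical concept sets.
#' @param mode `"exact_overlap"` or `"max_overlap"`.
#' @return An object of class `aligned_coding`: `items` (concept texts, fixed
#'   order), `labels` (items x raters integer matrix), `mode`, `rater_ids`.
#' @export
align_categories <- function(codings, mode = c("exact_overlap", "max_overlap")) {
  mode <- match.arg(mode)
  stopifnot(length(codings) >= 2L,
            all(vapply(codings, inherits, logical(1), "rater_coding")))
  item_sets <- lapply(codings, function(cd) cd$assignments$concept)
  items <- sort(item_sets[[1L]])
  for (s in item_sets[-1L]) {
    if (!identical(sort(s), items)) {
      diff <- union(setdiff(items, s), setdiff(s, items))
      stop_camnet(paste("raters cover different item sets; symmetric difference:",
                        paste(sort(diff), collapse = ", ")), "camnet_coding_error")
    }
  }
  rater_ids <- vapply(codings, `[[`, character(1), "rater_id")
  raw <- vapply(codings, function(cd) {
    cd$assignments$category[match(items, cd$assignments$concept)]
  }, character(length(items)))
  raw <- matrix(raw, nrow = length(items),
                dimnames = list(NULL, rater_ids))

  n_cat <- apply(raw, 2L, function(col) length(unique(col)))
  anchor <- which.max(n_cat)  # first max: deterministic
  # categories ordered by first occurrence along the fixed item list, so the
  # alignment (and every tie-break) is invariant to the labels raters chose
  anchor_labels <- unique(raw[, anchor])
  labels <- matrix(NA_integer_, nrow(raw), ncol(raw),
                   dimnames = dimnames(raw))
  labels[, anchor] <- match(raw[, anchor], anchor_labels)
  next_index <- length(anchor_labels)

  for (r in setdiff(seq_len(ncol(raw)), anchor)) {
    cats <- unique(raw[, r])
    overlap <- matrix(0L, length(cats), length(anchor_labels),
                      dimnames = list(cats, anchor_labels))
    for (i in seq_along(cats)) for (j in seq_along(anchor_labels)) {
      overlap[i, j] <- sum(raw[, r] == cats[i] & labels[, anchor] == j)
    }
    map <- rep(NA_integer_, length(cats))
    if (mode == "exact_overlap") {
      # perfect match: identical member sets only
      ref_sizes <- vapply(seq_along(anchor_labels),
                          function(j) sum(labels[, anchor] == j), integer(1))
      for (i in seq_along(cats)) {
        size_i <- sum(raw[, r] == cats[i])
        hit <- which(overlap[i, ] == size_i & ref_sizes == size_i)
        if (length(hit) == 1L) map[i] <- hit
      }
    } else {
      map <- assignment_max_overlap(overlap)
    }
    fresh <- which(is.na(map))
    for (i in fresh) { next_index <- next_index + 1L; map[i] <- next_index }
    labels[, r] <- map[match(raw[, r], cats)]
  }
  structure(list(items = items, labels = labels, mode = mode,
                 rater_ids = rater_ids), class = "aligned_coding")
}

# one-to-one assignment of rows (rater categories) to columns (reference
# categories) maximizing the total overlap; zero-overlap rows stay unassigned
assignment_max_overlap <- function(overlap) {
  nr <- nrow(overlap); nc <- ncol(overlap)
  edges <- which(overlap > 0L, arr.ind = TRUE)
  map <- rep(NA_integer_, nr)
  if (!nrow(edges)) return(map)
  g <- igraph::make_bipartite_graph(
    types = rep(c(FALSE, TRUE), c(nr, nc)),
    edges = as.vector(t(cbind(edges[, 1L], nr + edges[, 2L]))))
  m <- igraph::max_bipartite_match(g, types = rep(c(FALSE, TRUE), c(nr, nc)),
                                   weights = overlap[edges])
  partner <- m$matching[seq_len(nr)]
  ok <- !is.na(partner)
  map[ok] <- partner[ok] - nr
  map
}

#' Cohen's kappa for one rater pair
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement
#' proportion on the aligned labels and `p_e` the chance agreement from the
#' two raters' marginal category distributions. In the degenerate case
#' `p_e = 1` (a single shared category), kappa is reported as 1 when agreement
#' is perfect and 0 otherwise, with a `degenerate` attribute set.
#'
#' @param aligned An [align_categories()] result.
#' @param pair Length-2 vector of rater ids or column indices.
#' @return Kappa (numeric scalar, at most 1).
#' @export
cohen_kappa <- function(aligned, pair = c(1L, 2L)) {
  stopifnot(inherits(aligned, "aligned_coding"), length(pair) == 2L)
  if (is.character(pair)) pair <- match(pair, aligned$rater_ids)
  a <- aligned$labels[, pair[1L]]
  b <- aligned$labels[, pair[2L]]
  n <- length(a)
  if (n < 2L) stop_camnet("kappa needs at least 2 items", "camnet_coding_error")
  p_o <- mean(a == b)
  cats <- union(a, b)
  p_e <- sum(vapply(cats, function(k) mean(a == k) * mean(b == k), numeric(1)))
  if (p_e >= 1 - 1e-12) {
    k <- if (p_o >= 1 - 1e-12) 1 else 0
    attr(k, "degenerate") <- TRUE
    return(k)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Fleiss' kappa with category-wise coefficients
#'
#' For N items, n raters and `n_ij` raters assigning item i to category j:
#' `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`, `P_bar = mean_i P_i`,
#' `p_j = sum_i n_ij / (N n)`, `P_bar_e = sum_j p_j^2`, and
#' `kappa = (P_bar - P_bar_e) / (1 - P_bar_e)`. Category-wise:
#' `kappa_j = 1 - sum_i n_ij (n - n_ij) / (N n (n - 1) p_j (1 - p_j))`.
#'
#' @param aligned An [align_categories()] result covering all raters.
#' @return A list with `kappa` (overall) and `category_kappa` (named numeric;
#'   `NaN` for categories with degenerate marginals).
#' @export
fleiss_kappa <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_coding"))
  lab <- aligned$labels
  if (any(is.na(lab))) stop_camnet("missing ratings", "camnet_coding_error")
  N <- nrow(lab); n <- ncol(lab)
  cats <- sort(unique(as.vector(lab)))
  nij <- vapply(cats, function(k) rowSums(lab == k), numeric(N))
  nij <- matrix(nij, nrow = N, dimnames = list(NULL, cats))
  P_i <- (rowSums(nij^2) - n) / (n * (n - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(nij) / (N * n)
  P_e <- sum(p_j^2)
  kappa <- if (P_e >= 1 - 1e-12) {
    if (P_bar >= 1 - 1e-12) 1 else 0
  } else (P_bar - P_e) / (1 - P_e)
  denom <- N * n * (n - 1) * p_j * (1 - p_j)
  cat_kappa <- ifelse(denom > 0,
                      1 - colSums(nij * (n - nij)) / denom, NaN)
  list(kappa = kappa, category_kappa = setNames(cat_kappa, cats))
}

#' Full reliability report for a set of rater codings
#'
#' Computes every pairwise Cohen's kappa under both alignment modes, Fleiss'
#' kappa with category-wise coefficients (on the max_overlap alignment of all
#' raters), and per-category member summaries for rater training.
#'
#' @param codings A list of [rater_coding()] objects.
#' @return A list of class `cam_reliability_report` with `coefficients`
#'   (tibble: `statistic`, `raters`, `category`, `value`) and `categories`
#'   (tibble: shared category index, member concepts, number of raters using
#'   it).
#' @export
reliability_report <- function(codings) {
  stopifnot(length(codings) >= 2L)
  ids <- vapply(codings, `[[`, character(1), "rater_id")
  rows <- list()
  pairs <- combn(seq_along(codings), 2L)
  for (mode in c("exact_overlap", "max_overlap")) {
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      al <- align_categories(codings[c(i, j)], mode = mode)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        statistic = paste0("cohen_kappa_", mode),
        raters = paste(ids[i], ids[j], sep = "|"),
        category = NA_character_,
        value = as.numeric(cohen_kappa(al, c(1L, 2L))))
    }
  }
  al_all <- align_categories(codings, mode = "max_overlap")
  fl <- fleiss_kappa(al_all)
  rows[[length(rows) + 1L]] <- tibble::tibble(
    statistic = "fleiss_kappa", raters = paste(ids, collapse = "|"),
    category = NA_character_, value = fl$kappa)
  for (k in names(fl$category_kappa)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      statistic = "category_kappa", raters = paste(ids, collapse = "|"),
      category = k, value = unname(fl$category_kappa[k]))
  }
  members <- dplyr::bind_rows(lapply(sort(unique(as.vector(al_all$labels))), function(k) {
    used_by <- colSums(al_all$labels == k) > 0
    tibble::tibble(category = as.character(k),
                   members = paste(sort(unique(
                     al_all$items[rowSums(al_all$labels == k) > 0])), collapse = "; "),
                   n_raters = sum(used_by))
  }))
  structure(list(coefficients = dplyr::bind_rows(rows), categories = members),
            class = "cam_reliability_report")
}

#' @export
print.cam_reliability_report <- function(x, ...) {
  print(x$coefficients)
  invisible(x)
}
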