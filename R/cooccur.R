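#' Per-CAM presence of a concept label
#'
#' @param cams A `cam_set`.
#' @param label Concept text (normalized before matching).
#' @return Logical vector, one entry per CAM: whether the CAM contains at
#'   least one concept with that text.
#' @keywords internal
concept_presence <- function(cams, label) {
  if (is.na(label) || !nzchar(trimws(label)))
    stop_camnet("concept label must be non-empty", "camnet_integrity_error")
  label <- normalize_text(label)
  vapply(cams$cams, function(cm) label %in% normalize_text(cm$concepts$text),
         logical(1))
}

#' Build a 2x2 presence contingency table for two concepts
#'
#' Presence is binary per CAM: a CAM counts once however many instances of
#' the concept it contains. Cells: `a` = both concepts present, `b` = first
#' only, `c` = second only, `d` = neither; `a+b+c+d` = number of CAMs.
#'
#' @param cams A `cam_set` (normally after summarization).
#' @param concept_a,concept_b Concept labels.
#' @return An object of class `contingency_table` with fields `a`,`b`,`c`,`d`
#'   and `labels`.
#' @export
build_contingency <- function(cams, concept_a, concept_b) {
  stopifnot(inherits(cams, "cam_set"))
  pa <- concept_presence(cams, concept_a)
  pb <- concept_presence(cams, concept_b)
  structure(list(a = sum(pa & pb), b = sum(pa & !pb),
                 c = sum(!pa & pb), d = sum(!pa & !pb),
                 labels = c(concept_a, concept_b)), class = "contingency_table")
}

#' Phi coefficient of a 2x2 table
#'
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`, with a p-value from the
#' 1-df chi-squared statistic `chi2 = N * phi^2` (Pearson, no continuity
#' correction). When any expected cell count is below 5 the result carries a
#' small-cell flag and a Fisher exact p-value alongside.
#'
#' @param t A `contingency_table` (or a list with `a`,`b`,`c`,`d`).
#' @return A list: `phi`, `chisq`, `p`, `n`, `small_cells` (flag),
#'   `p_fisher` (`NA` unless flagged).
#' @export
phi_coefficient <- function(t) {
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0))
    stop_camnet("phi undefined: a marginal of the 2x2 table is zero",
                "camnet_phi_error")
  phi <- (a * d - b * c) / sqrt(prod(as.numeric(marg)))
  chisq <- n * phi^2
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  expected <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  small <- any(expected < 5)
  p_fisher <- if (small)
    fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value else NA_real_
  list(phi = phi, chisq = chisq, p = p, n = n,
       small_cells = small, p_fisher = p_fisher)
}

eligible_concepts <- function(cams, min_n) {
  pres <- lapply(cams$cams, function(cm) unique(normalize_text(cm$concepts$text)))
  tab <- table(unlist(pres))
  sort(names(tab)[tab >= min_n])
}

#' Pairwise concept co-occurrence matrix
#'
#' Builds the 2x2 presence table and phi coefficient for every pair of
#' concepts drawn in at least `min_n` CAMs. The long-format output is
#' heat-map ready; pairs with a zero marginal are flagged undefined (`NA`
#' phi). An optional Benjamini-Hochberg adjusted p column is included
#' (`p_adj`); raw p-values are not multiplicity-adjusted.
#'
#' @param cams A `cam_set` (normally after summarization).
#' @param min_n Minimum number of CAMs a concept must appear in (>= 1).
#' @return A list with `pairs` (tibble `concept_a`, `concept_b`, `a`, `b`,
#'   `c`, `d`, `phi`, `p`, `p_adj`, `small_cells`) and `matrix` (symmetric phi
#'   matrix, unit diagonal).
#' @export
cooccurrence_matrix <- function(cams, min_n = 1L) {
  stopifnot(inherits(cams, "cam_set"), min_n >= 1L)
  labs <- eligible_concepts(cams, min_n)
  m <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  diag(m) <- 1
  rows <- list()
  if (length(labs) >= 2L) for (i in seq_len(length(labs) - 1L)) for (j in (i + 1L):length(labs)) {
    ct <- build_contingency(cams, labs[i], labs[j])
    res <- tryCatch(phi_coefficient(ct), camnet_phi_error = function(e) NULL)
    phi <- if (is.null(res)) NA_real_ else res$phi
    m[i, j] <- m[j, i] <- phi
    rows[[length(rows) + 1L]] <- tibble::tibble(
      concept_a = labs[i], concept_b = labs[j],
      a = ct$a, b = ct$b, c = ct$c, d = ct$d,
      phi = phi, p = if (is.null(res)) NA_real_ else res$p,
      small_cells = if (is.null(res)) NA else res$small_cells)
  }
  pairs <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(concept_a = character(), concept_b = character(),
                   a = integer(), b = integer(), c = integer(), d = integer(),
                   phi = numeric(), p = numeric(), small_cells = logical())
  pairs$p_adj <- stats::p.adjust(pairs$p, method = "BH")
  list(pairs = pairs[, c("concept_a", "concept_b", "a", "b", "c", "d",
                         "phi", "p", "p_adj", "small_cells")],
       matrix = m)
}

#' Hierarchical clustering of CAMs by valence profiles
#'
#' For every concept drawn at least twice in the set, the per-CAM mean
#' valence is computed, columns are z-transformed (over the CAMs that drew the
#' concept), missing entries are imputed at the grand mean (0 after the
#' z-transform, flagged), and the CAMs are clustered agglomeratively with
#' Euclidean distance and Ward's method. Setting `transpose = TRUE` clusters
#' concepts over CAM profiles instead.
#'
#' @param cams A `cam_set` with at least 2 CAMs (normally after
#'   summarization).
#' @param k Optional number of flat clusters to cut.
#' @param min_times Minimum total number of times a concept must be drawn
#'   (default 2).
#' @param transpose Cluster concepts instead of CAMs.
#' @param ambivalent_policy Policy for numeric valences.
#' @return A list of class `cam_valence_clusters`: `hclust` (merge heights),
#'   `labels` (named cluster assignment when `k` given, else `NULL`),
#'   `features` (z-scored feature matrix used), `imputed` (logical matrix
#'   flagging grand-mean imputations), `profiles` (tibble of average z-scores
#'   per concept per cluster, when `k` given).
#' @export
valence_clusters <- function(cams, k = NULL, min_times = 2L, transpose = FALSE,
                             ambivalent_policy = "as_zero") {
  stopifnot(inherits(cams, "cam_set"))
  if (length(cams$cams) < 2L)
    stop_camnet("valence clustering needs at least 2 CAMs", "camnet_cluster_error")
  tab <- concept_table(cams)
  tab$text <- normalize_text(tab$text)
  counts <- table(tab$text)
  keep <- sort(names(counts)[counts >= min_times])
  if (length(keep) < 2L)
    stop_camnet("fewer than 2 concepts drawn at least min_times times",
                "camnet_cluster_error")
  tab <- tab[tab$text %in% keep, ]
  tab$value <- numeric_valence(tab$valence, tab$ambivalent, ambivalent_policy)
  mean_val <- tab |>
    dplyr::group_by(.data$cam_id, .data$text) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  cam_ids <- vapply(cams$cams, `[[`, character(1), "cam_id")
  X <- matrix(NA_real_, length(cam_ids), length(keep),
              dimnames = list(cam_ids, keep))
  X[cbind(match(mean_val$cam_id, cam_ids), match(mean_val$text, keep))] <- mean_val$value
  # column-wise z-transform over observed entries, then grand-mean imputation
  imputed <- is.na(X)
  for (j in seq_len(ncol(X))) {
    obs <- !is.na(X[, j])
    mu <- mean(X[obs, j]); s <- sd(X[obs, j])
    X[obs, j] <- if (is.na(s) || s == 0) 0 else (X[obs, j] - mu) / s
  }
  X[imputed] <- 0
  if (transpose) { X <- t(X); imputed <- t(imputed) }
  hc <- hclust(dist(X, method = "euclidean"), method = "ward.D2")
  labels <- NULL; profiles <- NULL
  if (!is.null(k)) {
    labels <- cutree(hc, k = k)
    prof <- dplyr::bind_rows(lapply(sort(unique(labels)), function(cl) {
      sub <- X[labels == cl, , drop = FALSE]
      tibble::tibble(cluster = cl, concept = colnames(X),
                     mean_z = colMeans(sub), n = nrow(sub))
    }))
    profiles <- prof
  }
  structure(list(hclust = hc, labels = labels, features = X,
                 imputed = imputed, profiles = profiles),
            class = "cam_valence_clusters")
}

#' Export a dendrogram as Newick text
#'
#' @param vc A `cam_valence_clusters` result (or an `hclust`).
#' @param path Optional file path; when omitted the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_dendrogram_newick <- function(vc, path = NULL) {
  hc <- if (inherits(vc, "cam_valence_clusters")) vc$hclust else vc
  phy <- ape::as.phylo(hc)
  nw <- ape::write.tree(phy)
  if (!is.null(path)) { writeLines(nw, path); return(invisible(nw)) }
  nw
}
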