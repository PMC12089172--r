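# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (memoized recursion, full
# shortest-path enumeration, Floyd-Warshall, set scans) so they share no code
# with the implementation under test.

# --- string distances ------------------------------------------------------

# OSA distance via memoized recursion on prefixes
osa_oracle <- function(s, t) {
  a <- strsplit(s, "")[[1]]
  b <- strsplit(t, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == 0) j else if (j == 0) i else {
      cost <- if (a[i] == b[j]) 0 else 1
      m <- min(rec(i - 1, j) + 1, rec(i, j - 1) + 1, rec(i - 1, j - 1) + cost)
      if (i > 1 && j > 1 && a[i] == b[j - 1] && a[i - 1] == b[j])
        m <- min(m, rec(i - 2, j - 2) + 1)
      m
    }
    memo[[key]] <- res
    res
  }
  rec(length(a), length(b))
}

# unrestricted Damerau-Levenshtein (distance with full transpositions)
dl_oracle <- function(s, t) {
  a <- utf8ToInt(s); b <- utf8ToInt(t)
  n <- length(a); m <- length(b)
  alphabet <- sort(unique(c(a, b)))
  da <- stats::setNames(rep(0L, length(alphabet)), alphabet)
  maxd <- n + m
  d <- matrix(0L, n + 2, m + 2)
  d[1, ] <- maxd; d[, 1] <- maxd
  d[2, 2:(m + 2)] <- 0:m
  d[2:(n + 2), 2] <- 0:n
  for (i in seq_len(n)) {
    db <- 0L
    for (j in seq_len(m)) {
      k <- da[as.character(b[j])]
      l <- db
      cost <- if (a[i] == b[j]) { db <- j; 0L } else 1L
      d[i + 2, j + 2] <- min(d[i + 1, j + 1] + cost,
                             d[i + 2, j + 1] + 1L,
                             d[i + 1, j + 2] + 1L,
                             d[k + 1, l + 1] + (i - k - 1L) + 1L + (j - l - 1L))
    }
    da[as.character(a[i])] <- i
  }
  d[n + 2, m + 2]
}

rand_word <- function(len, alphabet = letters[1:6]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# --- small random CAMs (built directly, independent of the synth module) ----

rand_small_cam <- function(n = sample(2:8, 1), p_edge = 0.45,
                           id = "t1", p_amb = 0.1) {
  ids <- sprintf("n%d", seq_len(n))
  amb <- runif(n) < p_amb
  concepts <- tibble::tibble(
    id = ids, text = sprintf("concept %s", letters[seq_len(n)]),
    valence = ifelse(amb, NA_integer_, sample(-3:3, n, replace = TRUE)),
    ambivalent = amb,
    x = 0, y = 0, predefined = FALSE, comment = "")
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) edges <- rbind(edges, c(i, j))
  }
  connectors <- if (is.null(edges)) NULL else tibble::tibble(
    id = sprintf("e%d", seq_len(nrow(edges))),
    source = ids[edges[, 1]], target = ids[edges[, 2]],
    strength = sample(c(-3:-1, 1:3), nrow(edges), replace = TRUE),
    directed = sample(c(TRUE, FALSE), nrow(edges), replace = TRUE))
  camnet::cam(cam_id = id, concepts = concepts, connectors = connectors)
}

cam_adjacency <- function(cm) {
  ids <- cm$concepts$id
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  cn <- cm$connectors
  if (nrow(cn)) for (k in seq_len(nrow(cn))) {
    A[cn$source[k], cn$target[k]] <- A[cn$target[k], cn$source[k]] <- 1L
  }
  A
}

cam_strengths <- function(cm) {
  ids <- cm$concepts$id
  S <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  cn <- cm$connectors
  if (nrow(cn)) for (k in seq_len(nrow(cn))) {
    S[cn$source[k], cn$target[k]] <- S[cn$target[k], cn$source[k]] <- cn$strength[k]
  }
  S
}

# all-pairs shortest path lengths by Floyd-Warshall
fw_dists <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  diag(D) <- 0
  D[A == 1L] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# connected component membership by flood fill
flood_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(A[v, ] == 1L & comp == 0L))
    }
  }
  stats::setNames(comp, rownames(A))
}

# enumerate all shortest paths between two nodes (vertex index sequences)
all_sp <- function(A, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  res <- list()
  grow <- function(path) {
    v <- path[length(path)]
    if (v == t) { res[[length(res) + 1L]] <<- path; return(invisible()) }
    for (w in which(A[v, ] == 1L)) {
      if (D[s, v] + 1 + D[w, t] == D[s, t] && D[s, w] == D[s, v] + 1)
        grow(c(path, w))
    }
  }
  grow(s)
  res
}

# betweenness centrality by exhaustive shortest-path enumeration
betweenness_oracle <- function(A) {
  n <- nrow(A)
  D <- fw_dists(A)
  btw <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in seq_len(n)) {
    if (t <= s) next
    paths <- all_sp(A, D, s, t)
    if (!length(paths)) next
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      for (v in inner) btw[v] <- btw[v] + 1 / length(paths)
    }
  }
  stats::setNames(btw, rownames(A))
}

# numeric valences with ambivalent-as-zero
oracle_valences <- function(cm) {
  v <- as.numeric(cm$concepts$valence)
  v[cm$concepts$ambivalent] <- 0
  stats::setNames(v, cm$concepts$id)
}

# brute-force neighborhood valence variants on the raw matrices
neighborhood_oracle <- function(cm, focus, variant) {
  A <- cam_adjacency(cm)
  S <- cam_strengths(cm)
  D <- fw_dists(A)
  val <- oracle_valences(cm)
  amb <- stats::setNames(cm$concepts$ambivalent, cm$concepts$id)
  ord <- if (variant %in% c(1, 3, 5)) 1 else 2
  nb <- names(val)[D[focus, ] >= 1 & D[focus, ] <= ord]
  if (!length(nb)) return(NA_real_)
  if (variant %in% c(1, 2)) return(mean(val[nb]))
  if (variant == 3) {
    w <- abs(S[focus, nb])
    return(sum(w * val[nb]) / sum(w))
  }
  if (variant == 4) {
    idx <- stats::setNames(seq_len(nrow(A)), rownames(A))
    w <- vapply(nb, function(id) {
      paths <- all_sp(A, D, idx[focus], idx[id])
      max(vapply(paths, function(p) {
        pr <- 1
        for (k in seq_len(length(p) - 1)) pr <- pr * abs(S[p[k], p[k + 1]]) / 3
        pr
      }, numeric(1)))
    }, numeric(1))
    return(sum(w * val[nb]) / sum(w))
  }
  carriers <- sum(!amb[nb] & val[nb] != 0)
  if (carriers == 0) return(NA_real_)
  sum(val[nb]) / carriers
}

# presence scan for contingency cells
contingency_oracle <- function(cams, la, lb) {
  norm <- function(x) gsub("[[:space:]]+", " ", tolower(trimws(x)))
  pa <- vapply(cams$cams, function(cm) norm(la) %in% norm(cm$concepts$text), logical(1))
  pb <- vapply(cams$cams, function(cm) norm(lb) %in% norm(cm$concepts$text), logical(1))
  c(a = sum(pa & pb), b = sum(pa & !pb), c = sum(!pa & pb), d = sum(!pa & !pb))
}

# random rater codings over shared items
rand_codings <- function(n_items = 20, n_raters = 2, n_cat = 4, prefix = "r") {
  items <- sprintf("item%02d", seq_len(n_items))
  lapply(seq_len(n_raters), function(r) {
    camnet::rater_coding(paste0(prefix, r), stats::setNames(
      sample(LETTERS[seq_len(n_cat)], n_items, replace = TRUE), items))
  })
}
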