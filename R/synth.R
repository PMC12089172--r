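#' Default concept vocabulary for synthetic CAMs
#'
#' Sixty everyday mobility/climate-flavored terms, mostly single words so the
#' typo/synonym noise machinery has material to work with.
#'
#' @return Character vector of base terms.
#' @export
default_vocabulary <- function() {
  c("acceptance", "accountability", "adaptation", "awareness", "benefits",
    "bicycle", "bus", "car", "charging", "cheap", "climate", "comfort",
    "commute", "community", "congestion", "convenience", "cost", "crowding",
    "danger", "delay", "distance", "dreams", "efficiency", "emissions",
    "energy", "environment", "expensive", "family", "fear", "flexibility",
    "freedom", "fuel", "future", "habit", "health", "independence",
    "infrastructure", "innovation", "jobs", "nature", "noise", "parking",
    "policy", "pollution", "price", "privacy", "responsibility", "risk",
    "safety", "schedule", "speed", "stress", "subsidy", "tax", "technology",
    "time", "traffic", "transport", "trust", "weather")
}

#' Configuration of the synthetic CAM generator
#'
#' Describes a simulated drawing study: how many CAMs, which network topology
#' the predefined starting concepts induce (a single central concept yields a
#' star; two opposing predefined concepts yield two bridged clusters; a
#' predefined root yields a tree; no predefined structure yields a connected
#' mesh), and the valence model. Each CAM carries a latent attitude
#' `mu ~ Normal(mu0, tau)`; concept valences are
#' `clip(round(Normal(mu, sigma)), -3, 3)`, with an independent coin flip
#' (`p_ambivalent`) overriding the numeric draw by the ambivalent marker. In
#' the two-cluster topology the two clusters sit at `mu +- cluster_offset`,
#' mirroring supporting-within / opposing-between affect.
#'
#' Passing a length-2 `mu0` plants two attitude groups: the CAMs are split
#' evenly and each half draws its latent attitude around its own group mean
#' (ground truth records the group), which is what the clustering-recovery
#' checks consume.
#'
#' @param n_cams Number of CAMs.
#' @param topology One of `"star"`, `"two_cluster"`, `"tree"`, `"mesh"`,
#'   `"free"`.
#' @param n_concepts Length-2 integer range (min, max) of concepts per CAM,
#'   within 1..50.
#' @param mu0 Population mean attitude (length 1), or length-2 group means.
#' @param tau SD of the per-CAM latent attitude.
#' @param sigma SD of concept valences around the latent attitude.
#' @param p_ambivalent Probability a concept is ambivalent.
#' @param cluster_offset Valence offset of the two clusters (two_cluster
#'   only).
#' @param vocabulary Base terms; must cover the largest CAM.
#' @param p_typo Probability a concept text gets a planted typo (one adjacent
#'   transposition or one substitution, OSA distance exactly 1) in
#'   [inject_text_noise()].
#' @param p_synonym Probability a single-word concept text is replaced by a
#'   dictionary synonym in [inject_text_noise()].
#' @param synonyms Optional named list word -> synonyms used for synonym
#'   noise.
#' @param seed Integer master seed; every CAM derives its own stream from
#'   (seed, cam index), so regenerating with a different `n_cams` leaves the
#'   shared prefix unchanged.
#' @return A list of class `gen_config`.
#' @export
gen_config <- function(n_cams, topology = c("star", "two_cluster", "tree",
                                            "mesh", "free"),
                       n_concepts = c(8L, 16L), mu0 = 0, tau = 1, sigma = 1,
                       p_ambivalent = 0.05, cluster_offset = 2,
                       vocabulary = default_vocabulary(),
                       p_typo = 0, p_synonym = 0, synonyms = NULL, seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_cams >= 1L, length(n_concepts) == 2L,
            n_concepts[1L] >= 1L, n_concepts[2L] <= 50L,
            n_concepts[1L] <= n_concepts[2L],
            p_ambivalent >= 0, p_ambivalent <= 1,
            p_typo >= 0, p_typo <= 1, p_synonym >= 0, p_synonym <= 1,
            length(mu0) %in% c(1L, 2L))
  if (length(vocabulary) < n_concepts[2L])
    stop_camnet("vocabulary smaller than the largest CAM", "camnet_config_error")
  if (topology == "star" && n_concepts[1L] < 2L)
    stop_camnet("star topology needs at least 2 concepts", "camnet_config_error")
  if (topology == "two_cluster" && n_concepts[1L] < 2L)
    stop_camnet("two_cluster topology needs the 2 anchor concepts", "camnet_config_error")
  structure(list(n_cams = as.integer(n_cams), topology = topology,
                 n_concepts = as.integer(n_concepts), mu0 = as.numeric(mu0),
                 tau = tau, sigma = sigma, p_ambivalent = p_ambivalent,
                 cluster_offset = cluster_offset, vocabulary = vocabulary,
                 p_typo = p_typo, p_synonym = p_synonym, synonyms = synonyms,
                 seed = as.integer(seed)), class = "gen_config")
}

draw_valence <- function(n, mu, sigma) {
  as.integer(pmax(-3L, pmin(3L, round(stats::rnorm(n, mu, sigma)))))
}

generate_one_cam <- function(cfg, i, group) {
  withr::with_seed(derive_seed(cfg$seed, i), {
    n_range <- seq(cfg$n_concepts[1L], cfg$n_concepts[2L])
    n <- if (length(n_range) == 1L) n_range else sample(n_range, 1L)
    mu <- stats::rnorm(1L, cfg$mu0[group], cfg$tau)
    texts <- sample(cfg$vocabulary, n)
    ids <- sprintf("c%d", seq_len(n))
    cluster <- rep(0L, n)
    edges <- NULL  # rows: (src idx, tgt idx, strength)
    pos_strength <- function(k) sample(1:3, k, replace = TRUE)
    if (cfg$topology == "star") {
      edges <- cbind(rep(1L, n - 1L), seq(2L, n), pos_strength(n - 1L))
    } else if (cfg$topology == "two_cluster") {
      cluster[1L] <- 1L; cluster[2L] <- 2L
      if (n > 2L) for (j in 3L:n) {
        cl <- sample(1:2, 1L)
        cluster[j] <- cl
        members <- which(cluster[seq_len(j - 1L)] == cl)
        attach_to <- if (length(members) == 1L) members else sample(members, 1L)
        edges <- rbind(edges, c(attach_to, j, pos_strength(1L)))
      }
      edges <- rbind(edges, c(1L, 2L, sample(-3:-1, 1L)))  # opposing bridge
    } else if (cfg$topology == "tree") {
      if (n > 1L) for (j in 2L:n)
        edges <- rbind(edges, c(sample(j - 1L, 1L), j, pos_strength(1L)))
    } else {  # mesh / free: random recursive backbone + extra edges
      if (n > 1L) for (j in 2L:n)
        edges <- rbind(edges, c(sample(j - 1L, 1L), j, pos_strength(1L)))
      p_extra <- if (cfg$topology == "mesh") 0.15 else 0.05
      if (n > 2L) for (a in 1L:(n - 1L)) for (b in (a + 1L):n) {
        present <- any(edges[, 1L] == a & edges[, 2L] == b)
        if (!present && stats::runif(1L) < p_extra)
          edges <- rbind(edges, c(a, b, pos_strength(1L)))
      }
    }
    mu_concept <- mu + ifelse(cluster == 1L, cfg$cluster_offset,
                              ifelse(cluster == 2L, -cfg$cluster_offset, 0))
    valence <- draw_valence(n, mu_concept, cfg$sigma)
    ambivalent <- stats::runif(n) < cfg$p_ambivalent
    valence[ambivalent] <- NA_integer_
    predefined <- rep(FALSE, n)
    if (cfg$topology %in% c("star", "tree")) predefined[1L] <- TRUE
    if (cfg$topology == "two_cluster") predefined[1:2] <- TRUE
    concepts <- tibble::tibble(
      id = ids, text = texts, comment = "",
      valence = valence, ambivalent = ambivalent,
      x = round(stats::runif(n, 0, 800)), y = round(stats::runif(n, 0, 600)),
      predefined = predefined)
    connectors <- if (is.null(edges)) NULL else tibble::tibble(
      id = sprintf("e%d", seq_len(nrow(edges))),
      source = ids[edges[, 1L]], target = ids[edges[, 2L]],
      strength = as.integer(edges[, 3L]), directed = FALSE)
    cm <- cam(cam_id = sprintf("cam_%04d", i),
              participant_id = sprintf("p%04d", i),
              topic = cfg$topology, concepts = concepts,
              connectors = connectors)
    list(cam = cm, mu = mu,
         cluster = setNames(cluster, ids))
  })
}

#' Generate a synthetic CAM set with ground truth
#'
#' Realizes the configured topology structurally (star: every concept
#' adjacent to the predefined central concept; two_cluster: two predefined
#' anchors, each further concept attached inside one anchor's cluster, a
#' single opposing bridge between the anchors; tree: random recursive tree
#' from the predefined root; mesh/free: random recursive backbone plus extra
#' edges). Connector strengths are uniform in {+1,+2,+3} within clusters and
#' {-3,-2,-1} on the two-cluster bridge. Every generated CAM passes the
#' invariants of the data model and the study configuration returned in
#' `config`.
#'
#' @param cfg A [gen_config()].
#' @return A list of class `cam_synth`: `cams` (a `cam_set`), `truth`
#'   (per-CAM latent attitude `mu`, attitude `group`, per-concept `cluster`
#'   membership), and `config` (the matching [study_config()]).
#' @export
generate_cam_set <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  groups <- if (length(cfg$mu0) == 2L)
    rep(1:2, length.out = cfg$n_cams) else rep(1L, cfg$n_cams)
  res <- lapply(seq_len(cfg$n_cams), function(i) generate_one_cam(cfg, i, groups[i]))
  cams <- cam_set(lapply(res, `[[`, "cam"))
  truth <- list(
    mu = vapply(res, `[[`, numeric(1), "mu"),
    group = groups,
    cluster = lapply(res, `[[`, "cluster"))
  names(truth$cluster) <- vapply(res, function(r) r$cam$cam_id, character(1))
  cfg_study <- study_config(
    min_num_nodes = min(cfg$n_concepts[1L], 50L), max_num_words = 3L,
    max_length_chars = 60L, enable_ambivalent = TRUE,
    enable_arrows = TRUE, bidirectional_default = TRUE,
    only_straight_con = FALSE)
  structure(list(cams = cams, truth = truth, config = cfg_study),
            class = "cam_synth")
}

# one planted typo at OSA distance exactly 1: adjacent transposition of two
# distinct characters when possible, otherwise a single substitution
make_typo <- function(word) {
  ch <- strsplit(word, "")[[1L]]
  n <- length(ch)
  pos <- which(ch[-n] != ch[-1L] & ch[-n] != " " & ch[-1L] != " ")
  if (length(pos) && stats::runif(1L) < 0.5) {
    p <- if (length(pos) == 1L) pos else sample(pos, 1L)
    ch[c(p, p + 1L)] <- ch[c(p + 1L, p)]
  } else {
    p <- sample(n, 1L)
    repl <- setdiff(letters, ch[p])
    ch[p] <- sample(repl, 1L)
  }
  paste(ch, collapse = "")
}

#' Inject planted text noise into a CAM set
#'
#' Replaces a recorded fraction of concept texts by typo'd variants (OSA
#' distance exactly 1 from the base term) and/or dictionary synonyms, and
#' returns the planted grouping so summarization-recovery can be scored.
#' Predefined concepts are left untouched.
#'
#' @param x A `cam_set` or `cam_synth`.
#' @param cfg The [gen_config()] (uses `p_typo`, `p_synonym`, `synonyms`,
#'   `seed`).
#' @return A list: `cams` (noised `cam_set`), `planted` (tibble `cam_id`,
#'   `concept_id`, `base`, `noisy`, `kind`).
#' @export
inject_text_noise <- function(x, cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  cams <- if (inherits(x, "cam_synth")) x$cams else x
  stopifnot(inherits(cams, "cam_set"))
  planted <- list()
  out <- lapply(seq_along(cams$cams), function(i) {
    cm <- cams$cams[[i]]
    withr::with_seed(derive_seed(cfg$seed, i, salt = 7L), {
      co <- cm$concepts
      for (j in seq_len(nrow(co))) {
        if (co$predefined[j]) next
        base <- co$text[j]
        u <- stats::runif(1L)
        if (u < cfg$p_typo) {
          noisy <- make_typo(base)
          co$text[j] <- noisy
          planted[[length(planted) + 1L]] <<- tibble::tibble(
            cam_id = cm$cam_id, concept_id = co$id[j], base = base,
            noisy = noisy, kind = "typo")
        } else if (u < cfg$p_typo + cfg$p_synonym &&
                   !is.null(cfg$synonyms) &&
                   base %in% names(cfg$synonyms) &&
                   length(cfg$synonyms[[base]])) {
          syns <- cfg$synonyms[[base]]
          noisy <- if (length(syns) == 1L) syns else sample(syns, 1L)
          co$text[j] <- noisy
          planted[[length(planted) + 1L]] <<- tibble::tibble(
            cam_id = cm$cam_id, concept_id = co$id[j], base = base,
            noisy = noisy, kind = "synonym")
        }
      }
      cm$concepts <- co
      cm
    })
  })
  list(cams = cam_set(out, provenance = cams$provenance),
       planted = if (length(planted)) dplyr::bind_rows(planted) else
         tibble::tibble(cam_id = character(), concept_id = character(),
                        base = character(), noisy = character(),
                        kind = character()))
}
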