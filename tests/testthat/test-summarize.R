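test_that("OSA distance reproduces worked values and degenerate cases", {
  expect_identical(osa_distance("dreams", "dreasm"), 1L)
  expect_identical(osa_distance("abc", "abc"), 0L)
  expect_identical(osa_distance("", "abc"), 3L)
  # OSA restriction: "ca"/"abc" is 3 under OSA but 2 unrestricted
  expect_identical(osa_distance("ca", "abc"), 3L)
  expect_identical(dl_oracle("ca", "abc"), 2L)
})

test_that("OSA matches the recursive oracle and is symmetric on random pairs", {
  withr::with_seed(7, {
    for (rep in 1:120) {
      s <- rand_word(sample(0:7, 1))
      t <- rand_word(sample(0:7, 1))
      d <- osa_distance(s, t)
      expect_identical(d, as.integer(osa_oracle(s, t)))
      expect_identical(d, osa_distance(t, s))
      expect_identical(d == 0L, s == t)
    }
  })
})

test_that("distance suggestions use single-linkage closure over OSA links", {
  g <- suggest_by_distance(c("dreams", "dreasm", "tree"), max_dist = 1)
  expect_identical(sort(g$member), c("dreams", "dreasm"))
  expect_identical(unique(g$group), 1L)

  expect_identical(nrow(suggest_by_distance(
    c("elephant", "parliament", "xylophone"), max_dist = 1)), 0L)

  # chain aaab - aaba (transposition), aaba - aabc: closure pulls all three in
  ch <- suggest_by_distance(c("aaab", "aaba", "aabc"), max_dist = 1)
  expect_identical(sort(ch$member), c("aaab", "aaba", "aabc"))
  # brute-force component check
  u <- c("aaab", "aaba", "aabc")
  link <- outer(u, u, Vectorize(function(x, y) osa_oracle(x, y) <= 1))
  comp <- flood_components(ifelse(link & !diag(3), 1L, 0L) |>
                             (\(m) { dimnames(m) <- list(u, u); m })())
  expect_identical(length(unique(comp)), 1L)
})

test_that("term search supports POSIX classes and case folding", {
  expect_identical(search_terms(c("co2 tax", "heat"), "[[:digit:]]"), "co2 tax")
  expect_identical(search_terms(c("co2 tax", "heat"), "zzz"), character())
  expect_identical(search_terms(c("War", "warm"), "^war$"), "war")
  expect_identical(search_terms(c("War", "warm"), "^war$", ignore_case = FALSE),
                   "war")  # normalization folds case before matching
  expect_error(search_terms("x", "("), class = "camnet_pattern_error")
})

test_that("synonym grouping links overlapping synonym sets of single words", {
  dict <- read_synonym_dictionary(system.file("extdata", "synonyms_en.json",
                                              package = "camnet"))
  g <- synonym_groups(c("war", "conflict"), dict)
  expect_identical(sort(g$member), c("conflict", "war"))
  # multi-word texts never participate
  g2 <- synonym_groups(c("world war", "conflict"), dict)
  expect_identical(nrow(g2), 0L)
  # only overlapping sets group
  g3 <- synonym_groups(c("big", "large", "transit"), dict)
  expect_identical(sort(g3$member), c("big", "large"))
  # dictionary symmetrization: reverse direction also links
  expect_true("accountability" %in% names(dict))
})

test_that("cosine similarity follows the formula and rejects zero vectors", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(3, 2, 1)), 10 / 14)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)),
               class = "camnet_similarity_error")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)),
               class = "camnet_similarity_error")
})

test_that("embedding suggestions match a brute-force all-pairs check", {
  vecs <- list("alpha" = c(1, 0, 0), "alpah" = c(0.99, 0.1, 0),
               "beta" = c(0, 1, 0), "betta" = c(0, 0.98, 0.2))
  res <- embedding_suggestions(names(vecs), vecs, threshold = 0.9)
  got <- split(res$groups$member, res$groups$group)
  expect_identical(sort(unname(vapply(got, paste, "", collapse = "+"))),
                   sort(c("alpah+alpha", "beta+betta")))
  # min pairwise similarity annotation
  for (gid in unique(res$groups$group)) {
    mem <- res$groups$member[res$groups$group == gid]
    sims <- combn(mem, 2, function(p) cosine_similarity(vecs[[p[1]]], vecs[[p[2]]]))
    expect_equal(unique(res$groups$score[res$groups$group == gid]), min(sims))
  }
  # threshold 1 with distinct directions yields nothing
  expect_identical(nrow(embedding_suggestions(
    c("alpha", "beta"), vecs, threshold = 1)$groups), 0L)
  # identical vectors pair at any threshold
  twin <- list(a = c(1, 1), b = c(2, 2))
  expect_identical(nrow(embedding_suggestions(c("a", "b"), twin, 1)$groups), 2L)
  # missing vectors are reported, not dropped silently
  expect_identical(embedding_suggestions(c("alpha", "ghost"), vecs, 0.5)$missing,
                   "ghost")
})

make_three_cam_set <- function() {
  mk <- function(id, texts, valences) {
    ids <- sprintf("%s_c%d", id, seq_along(texts))
    cam(cam_id = id, concepts = tibble::tibble(
      id = ids, text = texts, valence = valences),
      connectors = if (length(ids) > 1) tibble::tibble(
        id = sprintf("%s_e%d", id, seq_len(length(ids) - 1)),
        source = ids[1], target = ids[-1],
        strength = 1L, directed = FALSE) else NULL)
  }
  cam_set(list(
    mk("g1", c("cheap", "noise", "freedom"), c(2L, -1L, 3L)),
    mk("g2", c("Cheap", "price", "noise"), c(-2L, 0L, -2L)),
    mk("g3", c("expensive", "freedom"), c(-3L, 2L))))
}

test_that("apply_summary renames mapped concepts, optionally split by valence", {
  cams <- make_three_cam_set()
  map <- summary_map(c(cheap = "Cost", price = "Cost", expensive = "Cost"),
                     split_by_valence = TRUE)
  out <- apply_summary(cams, map)
  t1 <- out$cams[["g1"]]$concepts
  expect_identical(t1$text[1], "Cost_positive")
  expect_identical(t1$raw_text[1], "cheap")
  t2 <- out$cams[["g2"]]$concepts
  expect_identical(t2$text[1:2], c("Cost_negative", "Cost_neutral"))
  # structure untouched
  expect_identical(out$cams[["g1"]]$connectors, cams$cams[["g1"]]$connectors)
  expect_identical(t1$valence, cams$cams[["g1"]]$concepts$valence)
  # unmapped concepts untouched
  expect_identical(t1$text[2:3], c("noise", "freedom"))
})

test_that("apply_summary is idempotent and the empty map is the identity", {
  cams <- make_three_cam_set()
  empty <- summary_map(tibble::tibble(raw_text = character(), category = character()))
  same <- apply_summary(cams, empty)
  expect_identical(lapply(same$cams, function(c) c$concepts$text),
                   lapply(cams$cams, function(c) c$concepts$text))
  map <- summary_map(c(cheap = "Cost", noise = "Noise"), split_by_valence = TRUE)
  once <- apply_summary(cams, map)
  twice <- apply_summary(once, map)
  expect_identical(lapply(twice$cams, function(c) c$concepts),
                   lapply(once$cams, function(c) c$concepts))
})

test_that("unsummarized overview counts unmapped texts like a brute tally", {
  cams <- make_three_cam_set()
  full <- summary_map(c(cheap = "Cost", price = "Cost", expensive = "Cost",
                        noise = "Noise", freedom = "Freedom"))
  expect_identical(nrow(unsummarized_overview(cams, full)), 0L)
  none <- summary_map(tibble::tibble(raw_text = character(), category = character()))
  ov <- unsummarized_overview(cams, none)
  texts <- tolower(unlist(lapply(cams$cams, function(c) c$concepts$text)))
  expect_identical(sum(ov$n), length(texts))
  for (i in seq_len(nrow(ov)))
    expect_identical(ov$n[i], as.integer(sum(texts == ov$text[i])))
  # sorted by frequency desc then lexicographic (cheap/freedom/noise tie at 2)
  expect_identical(ov$text[1:3], c("cheap", "freedom", "noise"))
})

test_that("summary maps reject duplicates and empty categories, and survive CSV", {
  expect_error(summary_map(tibble::tibble(raw_text = c("a", "a"),
                                          category = c("X", "Y"))),
               class = "camnet_map_error")
  expect_error(summary_map(tibble::tibble(raw_text = "a", category = "")),
               class = "camnet_map_error")
  f <- withr::local_tempfile(fileext = ".csv")
  m <- summary_map(c(cheap = "Cost"))
  write_summary_map(m, f)
  expect_identical(read_summary_map(f)$entries, m$entries)
})
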