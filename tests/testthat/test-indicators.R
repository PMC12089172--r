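path_cam <- function() {
  cam("path", tibble::tibble(id = c("a", "b", "c"),
                             text = c("one", "two", "three"),
                             valence = c(1L, 2L, 3L)),
      tibble::tibble(id = c("e1", "e2"), source = c("a", "b"),
                     target = c("b", "c"), strength = c(1L, 2L)))
}

star_cam <- function(k = 5, leaf_val = rep(1L, k)) {
  ids <- c("hub", sprintf("l%d", seq_len(k)))
  cam("star", tibble::tibble(id = ids,
                             text = c("center", sprintf("leaf %d", seq_len(k))),
                             valence = c(0L, leaf_val)),
      tibble::tibble(id = sprintf("e%d", seq_len(k)), source = "hub",
                     target = ids[-1], strength = rep(2L, k)))
}

ind_val <- function(tab, name) tab$value[tab$indicator == name]

test_that("ambivalence policy maps valences as defined", {
  expect_identical(numeric_valence(3L, FALSE), 3)
  expect_identical(numeric_valence(NA_integer_, TRUE, "as_zero"), 0)
  expect_true(is.na(numeric_valence(NA_integer_, TRUE, "exclude")))
  expect_equal(mean(numeric_valence(c(3L, -3L, 0L, NA), c(F, F, F, T), "as_zero")), 0)
})

test_that("macro indicators follow their formulas on hand-built CAMs", {
  p <- macro_indicators(path_cam())
  expect_equal(ind_val(p, "density"), 2 / 3)
  expect_equal(ind_val(p, "diameter"), 2)
  expect_equal(ind_val(p, "mean_valence"), 2)
  expect_equal(ind_val(p, "num_nodes"), 3)
  expect_equal(ind_val(p, "num_links"), 2)
  expect_equal(ind_val(p, "central_node_valence"), 2)  # "b" has max degree

  four <- cam("four", tibble::tibble(id = letters[1:4], text = letters[1:4],
                                     valence = c(1L, 1L, 1L, 1L)),
              tibble::tibble(id = c("e1", "e2", "e3"),
                             source = c("a", "a", "a"),
                             target = c("b", "c", "d"), strength = 1L))
  expect_equal(ind_val(macro_indicators(four), "density"), 3 / 6)
  expect_equal(ind_val(macro_indicators(four), "pct_positive"), 1)
  expect_equal(ind_val(macro_indicators(four), "pct_negative"), 0)
})

test_that("valence class shares always sum to one exactly", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      m <- macro_indicators(rand_small_cam())
      expect_identical(sum(m$value[startsWith(m$indicator, "pct_")]), 1)
      expect_true(abs(ind_val(m, "mean_valence")) <= 3)
      d <- ind_val(m, "density")
      expect_true(is.na(d) || (d >= 0 && d <= 1))
    }
  })
})

test_that("central concept designation prefers explicit id, then predefined flag", {
  cm <- path_cam()
  m <- macro_indicators(cm, central_id = "c")
  expect_equal(ind_val(m, "central_node_valence"), 3)
  cm$concepts$predefined[1] <- TRUE  # "a"
  expect_equal(ind_val(macro_indicators(cm), "central_node_valence"), 1)
  expect_error(macro_indicators(cm, central_id = "zz"),
               class = "camnet_integrity_error")
})

test_that("micro indicators: star center/leaves and oracle betweenness", {
  st <- star_cam(5)
  mi <- micro_indicators(st, c("hub", "l1"))
  expect_equal(mi$value[mi$focus == "hub" & mi$indicator == "degree"], 5)
  expect_equal(mi$value[mi$focus == "l1" & mi$indicator == "betweenness"], 0)
  expect_error(micro_indicators(st, "nope"), class = "camnet_integrity_error")

  withr::with_seed(21, {
    for (rep in 1:15) {
      cm <- rand_small_cam(n = 6)
      A <- cam_adjacency(cm)
      got <- micro_indicators(cm, cm$concepts$id)
      bt <- betweenness_oracle(A)
      for (id in cm$concepts$id) {
        expect_equal(got$value[got$focus == id & got$indicator == "degree"],
                     sum(A[id, ]))
        expect_equal(got$value[got$focus == id & got$indicator == "betweenness"],
                     unname(bt[id]), tolerance = 1e-10)
      }
    }
  })
})

test_that("mezzo indicators find the obvious community structure", {
  tri2 <- cam("tri2", tibble::tibble(id = letters[1:6], text = letters[1:6],
                                     valence = c(1L, 1L, 1L, -1L, -1L, -1L)),
              tibble::tibble(id = sprintf("e%d", 1:6),
                             source = c("a", "b", "c", "d", "e", "f"),
                             target = c("b", "c", "a", "e", "f", "d"),
                             strength = 1L))
  mz <- mezzo_indicators(tri2)
  expect_equal(mz$value[mz$indicator == "num_components"], 2)
  sizes <- mz$value[mz$indicator == "community_size"]
  expect_identical(sizes, c(3, 3))
  mv <- mz$value[mz$indicator == "community_mean_valence"]
  expect_setequal(mv, c(1, -1))

  clique <- cam("k4", tibble::tibble(id = letters[1:4], text = letters[1:4],
                                     valence = 0L),
                tibble::tibble(id = sprintf("e%d", 1:6),
                               source = c("a", "a", "a", "b", "b", "c"),
                               target = c("b", "c", "d", "c", "d", "d"),
                               strength = 1L))
  mzc <- mezzo_indicators(clique)
  expect_identical(sum(mzc$indicator == "community_size"), 1L)
  expect_equal(mzc$value[mzc$indicator == "community_density"], 1)
})

test_that("greedy modularity recovers a planted two-block structure", {
  withr::with_seed(77, {
    n <- 12
    block <- rep(1:2, each = n / 2)
    ids <- sprintf("v%d", 1:n)
    edges <- NULL
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      p <- if (block[i] == block[j]) 0.9 else 0.05
      if (runif(1) < p) edges <- rbind(edges, c(i, j))
    }
    cm <- cam("planted", tibble::tibble(id = ids, text = ids, valence = 0L),
              tibble::tibble(id = sprintf("e%d", seq_len(nrow(edges))),
                             source = ids[edges[, 1]], target = ids[edges[, 2]],
                             strength = 1L))
    mz <- mezzo_indicators(cm)
    sizes <- sort(mz$value[mz$indicator == "community_size"])
    expect_identical(sizes, c(6, 6))
  })
})

test_that("neighborhood variants reproduce hand values", {
  st <- star_cam(3, leaf_val = c(2L, -1L, 3L))
  expect_equal(neighborhood_valence(st, "hub", 1), 4 / 3)
  # order 2 from a leaf reaches the hub and the other leaves
  expect_equal(neighborhood_valence(st, "l1", 2), (0 + -1 + 3) / 3)
  # all-neutral neighbors: v1 = 0 but v5 undefined
  neutral <- star_cam(3, leaf_val = c(0L, 0L, 0L))
  expect_equal(neighborhood_valence(neutral, "hub", 1), 0)
  v5 <- neighborhood_valence(neutral, "hub", 5)
  expect_true(is.na(v5))
  expect_true(isTRUE(attr(v5, "undefined")))
  # affect-adjusted: numerator sums all, denominator counts carriers
  mixed <- star_cam(4, leaf_val = c(2L, -1L, 0L, 0L))
  expect_equal(neighborhood_valence(mixed, "hub", 5), (2 - 1 + 0 + 0) / 2)
})

test_that("temporary removals shape the neighborhood; empty removal is identity", {
  # two clusters bridged: car side positive, transport side negative
  ids <- c("car", "fun", "free", "pt", "wait", "crowd")
  cm <- cam("two", tibble::tibble(
    id = ids, text = ids, valence = c(0L, 2L, 3L, 0L, -2L, -3L)),
    tibble::tibble(id = sprintf("e%d", 1:5),
                   source = c("car", "car", "pt", "pt", "car"),
                   target = c("fun", "free", "wait", "crowd", "pt"),
                   strength = c(2L, 1L, 2L, 3L, -2L)))
  # the bridge pulls opposing affect into pt's order-2 neighborhood:
  # with it cut, pt's neighborhood is clearly negative, car's positive
  expect_equal(neighborhood_valence(cm, "pt", 2), 0)  # (-2-3+0+2+3)/5
  v2_pt_cut <- neighborhood_valence(cm, "pt", 2,
                                    removed_edges = list(c("car", "pt")))
  expect_equal(v2_pt_cut, (-2 - 3) / 2)
  v2_car_cut <- neighborhood_valence(cm, "car", 2,
                                     removed_edges = list(c("car", "pt")))
  expect_equal(v2_car_cut, (2 + 3) / 2)
  expect_equal(neighborhood_valence(cm, "car", 2, removed_edges = list()),
               neighborhood_valence(cm, "car", 2))
  expect_error(neighborhood_valence(cm, "pt", 1, removed_nodes = "pt"),
               class = "camnet_integrity_error")
})

test_that("all six variants match the brute-force oracle on random CAMs", {
  withr::with_seed(5, {
    for (rep in 1:25) {
      cm <- rand_small_cam(n = sample(3:8, 1))
      focus <- sample(cm$concepts$id, 1)
      for (v in 1:6) {
        got <- neighborhood_valence(cm, focus, v)
        want <- neighborhood_oracle(cm, focus, v)
        if (is.na(want)) expect_true(is.na(got)) else
          expect_equal(as.numeric(got), want, tolerance = 1e-12)
      }
    }
  })
})

test_that("indicator summary aggregates across CAMs with correlations", {
  withr::with_seed(3, {
    cams <- cam_set(lapply(1:6, function(i) rand_small_cam(id = paste0("c", i))))
  })
  s <- indicator_summary(cams)
  expect_identical(nrow(s$per_cam), 60L)
  expect_true(all(c("mean", "sd", "n") %in% names(s$summary)))
  expect_true(all(s$correlations$r >= -1 & s$correlations$r <= 1))
})
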