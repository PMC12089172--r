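fixture_cam <- function() {
  cam(cam_id = "fix1", participant_id = "p1", topic = "mobility",
      concepts = tibble::tibble(
        id = c("a", "b", "c", "d", "e"),
        text = c("own car", "public transport", "cost", "freedom", "noise"),
        comment = c("", "daily", "", "", ""),
        valence = c(1L, -2L, NA, 3L, 0L),
        ambivalent = c(FALSE, FALSE, TRUE, FALSE, FALSE),
        x = c(10, 200, 90, 40, 300), y = c(20, 30, 200, 250, 150),
        predefined = c(TRUE, TRUE, FALSE, FALSE, FALSE)),
      connectors = tibble::tibble(
        id = c("e1", "e2", "e3", "e4"),
        source = c("a", "a", "b", "b"),
        target = c("c", "d", "e", "a"),
        strength = c(-2L, 3L, 1L, -1L),
        directed = c(FALSE, TRUE, FALSE, FALSE)))
}

test_that("minimal and malformed documents parse as specified", {
  one <- parse_cam('{"cam_id":"x","participant_id":"p",
    "concepts":[{"id":"n1","text":"idea","valence":0,
                 "position":{"x":1,"y":2},"predefined":false}],
    "connectors":[]}')
  expect_s3_class(one, "cam")
  expect_identical(nrow(one$concepts), 1L)
  expect_identical(nrow(one$connectors), 0L)

  bad <- '{"cam_id":"x","participant_id":"p",
    "concepts":[{"id":"n1","text":"idea","valence":0,"position":{"x":0,"y":0}}],
    "connectors":[{"id":"e1","source":"n1","target":"n9","strength":1}]}'
  expect_error(parse_cam(bad), "n9", class = "camnet_integrity_error")

  expect_error(parse_cam('{"participant_id":"p"}'), "cam_id",
               class = "camnet_parse_error")
})

test_that("legacy numeric ambivalent code maps to the ambivalent marker", {
  legacy <- '{"cam_id":"x","participant_id":"p",
    "concepts":[{"id":"n1","text":"mixed","valence":10,"position":{"x":0,"y":0}}],
    "connectors":[]}'
  cm <- parse_cam(legacy)
  expect_true(cm$concepts$ambivalent[1])
  expect_true(is.na(cm$concepts$valence[1]))
})

test_that("write_cam is canonical and round-trips, including ambivalence", {
  cm <- fixture_cam()
  js <- write_cam(cm)
  cm2 <- parse_cam(js)
  expect_true(camnet:::cam_equal(cm, cm2))
  # byte-identical across structurally equal CAMs: shuffle row order
  cm3 <- cm
  cm3$concepts <- cm3$concepts[5:1, ]
  cm3$connectors <- cm3$connectors[4:1, ]
  expect_identical(write_cam(cm3), js)
  # ambivalence survives the round trip as the explicit marker
  expect_match(js, '"valence":"ambivalent"', fixed = TRUE)
  expect_true(cm2$concepts$ambivalent[cm2$concepts$id == "c"])
})

test_that("parse-write identity holds on random CAMs", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      cm <- rand_small_cam(id = sprintf("r%d", rep))
      expect_true(camnet:::cam_equal(cm, parse_cam(write_cam(cm))))
    }
  })
})

test_that("structural invariants are enforced at construction", {
  co <- tibble::tibble(id = c("a", "b"), text = c("x", "y"), valence = c(0L, 0L))
  expect_error(cam("c", co, tibble::tibble(
    id = "e1", source = "a", target = "a", strength = 1L)),
    class = "camnet_integrity_error")
  expect_error(cam("c", co, tibble::tibble(
    id = "e1", source = "a", target = "b", strength = 0L)),
    class = "camnet_integrity_error")
  expect_error(cam("c", co, tibble::tibble(
    id = c("e1", "e2"), source = c("a", "b"), target = c("b", "a"),
    strength = c(1L, 2L))),
    class = "camnet_integrity_error")
  expect_error(cam("c", tibble::tibble(id = c("a", "a"), text = c("x", "y"),
                                       valence = c(0L, 0L)), NULL),
               class = "camnet_integrity_error")
})

test_that("validation against a study configuration flags each rule", {
  cm <- fixture_cam()
  cfg <- study_config(min_num_nodes = 6)
  v <- validate_against_config(cm, cfg)
  expect_identical(v$rule, "TOO_FEW_NODES")

  # disconnected concept
  cm2 <- cam("c2", tibble::tibble(id = c("a", "b", "x"),
                                  text = c("one", "two", "lonely"),
                                  valence = c(0L, 0L, 0L)),
             tibble::tibble(id = "e1", source = "a", target = "b", strength = 1L))
  v2 <- validate_against_config(cm2, study_config())
  expect_identical(v2$rule, "DISCONNECTED_CONCEPT")
  expect_identical(v2$element, "x")

  # feature switches
  cfg3 <- study_config(enable_ambivalent = FALSE, enable_arrows = FALSE,
                       only_straight_con = TRUE, max_num_words = 1)
  v3 <- validate_against_config(cm, cfg3)
  expect_setequal(unique(v3$rule),
                  c("AMBIVALENT_DISABLED", "ARROW_DISABLED",
                    "OPPOSING_DISABLED", "TOO_MANY_WORDS"))
  # compliant star CAM
  star <- cam("s", tibble::tibble(id = c("z", "l1", "l2"),
                                  text = c("hub", "leaf", "loaf"),
                                  valence = c(0L, 1L, -1L)),
              tibble::tibble(id = c("e1", "e2"), source = c("z", "z"),
                             target = c("l1", "l2"), strength = c(1L, 1L)))
  expect_identical(nrow(validate_against_config(star, study_config())), 0L)
})

test_that("validate_against_config agrees with independent rule predicates", {
  withr::with_seed(11, {
    cfg <- study_config(min_num_nodes = 4, max_num_words = 2,
                        max_length_chars = 30, enable_ambivalent = FALSE,
                        only_straight_con = TRUE)
    for (rep in 1:20) {
      cm <- rand_small_cam(id = sprintf("v%d", rep))
      v <- validate_against_config(cm, cfg)
      co <- cm$concepts; cn <- cm$connectors
      connected <- unique(c(cn$source, cn$target))
      expected <- c(
        if (nrow(co) < 4) "TOO_FEW_NODES",
        if (nrow(co) > 1) rep("DISCONNECTED_CONCEPT", sum(!co$id %in% connected)),
        rep("TOO_MANY_WORDS",
            sum(lengths(strsplit(trimws(co$text), "[[:space:]]+")) > 2)),
        rep("TOO_MANY_CHARS", sum(nchar(co$text) > 30)),
        rep("AMBIVALENT_DISABLED", sum(co$ambivalent)),
        rep("OPPOSING_DISABLED", sum(cn$strength < 0)))
      expect_identical(sort(v$rule), sort(expected))
    }
  })
})

test_that("edge-list export is lossless and re-importable", {
  cm <- fixture_cam()
  el <- to_edge_list(cm)
  expect_identical(nrow(el), 4L)
  empty <- cam("e", tibble::tibble(id = "a", text = "solo", valence = 0L), NULL)
  expect_identical(nrow(to_edge_list(empty)), 0L)

  rebuilt <- cam_from_tables(cm$concepts, el, cam_id = "fix1",
                             participant_id = "p1")
  g1 <- cam_igraph(cm); g2 <- cam_igraph(rebuilt)
  expect_true(igraph::is_isomorphic_to(g1, g2))
  expect_identical(to_edge_list(rebuilt)[, 1:3], el[, 1:3])
})

test_that("cam_set enforces unique ids and reads/writes directories", {
  cm <- fixture_cam()
  expect_error(cam_set(list(cm, cm)), class = "camnet_integrity_error")
  dir <- withr::local_tempdir()
  cs <- cam_set(list(cm))
  paths <- write_cam_set(cs, dir)
  cs2 <- read_cam_set(list.files(dir, full.names = TRUE))
  expect_true(camnet:::cam_equal(cs$cams[[1]], cs2$cams[[1]]))
})
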