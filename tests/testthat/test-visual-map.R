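chain3 <- function() stoichiometric_matrix(
  parse_reaction_list("v1: A => B\nv2: B => C"))

test_that("arrows layout places one node per species and one arrow per reaction", {
  map <- auto_layout(chain3(), "arrows")
  expect_equal(nrow(map$nodes), 3)
  expect_length(map$arrows, 2)
  expect_equal(vapply(map$arrows, function(a) nrow(a$sources) +
                        nrow(a$targets), 0L), c(2L, 2L))
  # determinism
  expect_identical(auto_layout(chain3(), "arrows"),
                   auto_layout(chain3(), "arrows"))
})

test_that("bars layout creates species bars then reaction bars in order", {
  m <- fixture_model("mini_krebs")
  map <- auto_layout(m$S, "bars")
  expect_equal(map$bars$id, c(m$species, names(m$rate_text)))
  expect_equal(map$bars$kind,
               c(rep("concentration", 4), rep("rate", 4)))
  expect_true(all(diff(map$bars$x) > 0))   # left to right
})

test_that("map_to_stoichiometry inverts auto_layout", {
  S <- chain3()
  expect_identical(map_to_stoichiometry(auto_layout(S, "arrows")), S)

  # hand-built two-substrate arrow gives a column with two -1 entries
  map <- visual_map(
    canvas = c(200, 200),
    nodes = tibble::tibble(id = c("A", "B", "C"), x = c(10, 50, 90),
                           y = 50, label = c("A", "B", "C")),
    arrows = list(list(id = "r1",
                       sources = tibble::tibble(node = c("A", "B"),
                                                mult = c(1, 1)),
                       targets = tibble::tibble(node = "C", mult = 1),
                       points = tibble::tibble(x = numeric(), y = numeric()),
                       thickness = 2, style = "solid")))
  S2 <- map_to_stoichiometry(map)
  expect_equal(unname(S2[, "r1"]), c(-1L, -1L, 1L))
})

test_that("round trip holds on random unit-coefficient networks", {
  set.seed(99)
  for (rep in 1:100) {
    rxns <- random_network(unit_coefficients = TRUE)
    S <- stoichiometric_matrix(rxns)
    expect_identical(map_to_stoichiometry(auto_layout(S, "arrows")), S)
  }
})

test_that("dangling arrow endpoints are rejected by name", {
  map <- auto_layout(chain3(), "arrows")
  map$arrows[[1]]$sources$node <- "ZZ"
  expect_error(map_to_stoichiometry(map), "dangling")
  expect_error(map_to_stoichiometry(map), "ZZ")
})

test_that("map XML round trip is structurally lossless", {
  # empty map
  empty <- visual_map(canvas = c(100, 80))
  f <- withr::local_tempfile(fileext = ".xml")
  write_map(empty, f)
  expect_equal(read_map(f)$map, empty)

  # mini-cycle with annotations, points and bindings
  m <- fixture_model("mini_krebs")
  map <- auto_layout(m$S, "arrows")
  map <- annotate_map(map, "text", 12, 20, text = "cycle")
  map <- annotate_map(map, "box", 5, 5, 50, 40)
  tc <- simulate_timecourse(m, seq(0, 10, by = 1))
  b <- default_bindings(map, as_plt(tc))
  write_map(map, f, b)
  rt <- read_map(f)
  expect_equal(rt$map, map)
  expect_equal(rt$bindings, b)
})

test_that("unknown XML elements are rejected with the element name", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines('<map width="10" height="10"><blob x="1"/></map>', f)
  expect_error(read_map(f), "unknown element 'blob'")
})

test_that("SVG export is deterministic with one element per object", {
  map <- auto_layout(chain3(), "arrows")
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  export_map(map, f1, "svg")
  export_map(map, f2, "svg")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  x <- xml2::read_xml(f1)
  xml2::xml_ns_strip(x)
  expect_length(xml2::xml_find_all(x, "//circle[@class='node']"), 3)
  expect_length(xml2::xml_find_all(x, "//line[@class='arrow']"), 2)
})

test_that("PNG export has exactly the canvas dimensions", {
  map <- auto_layout(chain3(), "arrows")
  f <- withr::local_tempfile(fileext = ".png")
  export_map(map, f, "png")
  img <- png::readPNG(f)
  expect_equal(dim(img)[1:2], rev(map$canvas))
})
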