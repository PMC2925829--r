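mini_tc_plt <- function(n = 11) {
  m <- fixture_model("mini_krebs")
  as_plt(simulate_timecourse(m, seq(0, 10, length.out = n)))
}

test_that("PLT files start with N1, N2 and a full title row", {
  m <- kinetic_model("v1: A => B\nv2: B => C", initial = c(A = 1),
                     parameters = c(kf_v1 = 1, kf_v2 = 1))
  plt <- as_plt(simulate_timecourse(m, c(0, 1, 2)))
  f <- withr::local_tempfile(fileext = ".plt")
  write_plt(plt, f)
  lines <- readLines(f)
  expect_equal(lines[[1]], "3")          # metabolites
  expect_equal(lines[[2]], "2")          # reactions
  titles <- strsplit(lines[[3]], "\t")[[1]]
  expect_length(titles, 1 + 3 + 2)
  expect_equal(titles[[1]], "X[0]")
})

test_that("PLT write/read round trip is numerically lossless", {
  m <- fixture_model("mini_krebs")
  plt <- as_plt(simulate_timecourse(m, seq(0, 33, length.out = 100)))
  f <- withr::local_tempfile(fileext = ".plt")
  write_plt(plt, f)
  back <- read_plt(f)
  expect_identical(as.matrix(as.data.frame(back)),
                   as.matrix(as.data.frame(plt)))
  expect_equal(attr(back, "titles"), attr(plt, "titles"))

  # branch PLT: the independent column is the varied parameter
  br <- continue_branch(fixture_model("mini_krebs"), "S_ext", 2, 10)
  pb <- as_plt(br)
  expect_equal(pb[["X[0]"]], br$S_ext)
})

test_that("malformed PLT files report the offending row", {
  f <- withr::local_tempfile(fileext = ".plt")
  writeLines(c("2", "1", "X[0]\tA\tB\tv1", "0\t1\t2\t3", "1\t1\t2"), f)
  expect_error(read_plt(f), "row 5")
  writeLines(c("2", "1", "X[0]\tA\tv1"), f)
  expect_error(read_plt(f), "row 3")
})

test_that("radius scaling reproduces the printed piecewise equation", {
  expect_equal(scale_radius(0.5, 1, 3, 10), 0)       # below minimum
  expect_equal(scale_radius(1, 1, 3, 10), 0)         # ramp start
  expect_equal(scale_radius(2, 1, 3, 10), 5)         # midpoint: r_max / 2
  expect_equal(scale_radius(3, 1, 3, 10), 10)        # ramp end: r_max
  expect_equal(scale_radius(99, 1, 3, 10), 10)       # clamped above
  expect_error(scale_radius(1, 3, 1, 10), "c_min < c_max")
  expect_error(scale_radius(1, 0, 1, -2), "r_max > 0")
})

test_that("thickness scaling is the same clamped-linear form", {
  expect_equal(scale_thickness(5, 0, 4, 8), 8)       # above maximum
  expect_equal(scale_thickness(0, 0, 4, 8), 0)       # ramp start
  expect_equal(scale_thickness(2, 0, 4, 8), 4)
  set.seed(31)
  v <- sort(runif(1000, -2, 6))
  h <- scale_thickness(v, 0.5, 4.5, 7)
  expect_true(all(h >= 0 & h <= 7))
  expect_true(all(diff(h) >= 0))                     # non-decreasing
  # continuity across the two break points
  eps <- 1e-9
  expect_lt(abs(scale_thickness(0.5 + eps, 0.5, 4.5, 7) -
                scale_thickness(0.5 - eps, 0.5, 4.5, 7)), 1e-6)
  expect_lt(abs(scale_thickness(4.5 + eps, 0.5, 4.5, 7) -
                scale_thickness(4.5 - eps, 0.5, 4.5, 7)), 1e-6)
})

test_that("one frame is rendered per PLT row with recomputable metadata", {
  plt <- mini_tc_plt(8)
  m <- fixture_model("mini_krebs")
  map <- auto_layout(m$S, "arrows")
  b <- default_bindings(map, plt)
  frames <- render_frames(map, b, plt)
  expect_length(frames, nrow(plt))
  # metadata equals an independent recomputation from PLT + bindings
  for (i in c(1, 4, 8)) {
    for (sp in map$nodes$id) {
      bs <- b$species[b$species$id == sp, ]
      expect_equal(frames[[i]]$radii[[sp]],
                   scale_radius(plt[[sp]][[i]], bs$cmin, bs$cmax, bs$rmax))
    }
    for (rx in vapply(map$arrows, function(a) a$id, "")) {
      brx <- b$reactions[b$reactions$id == rx, ]
      expect_equal(frames[[i]]$thicknesses[[rx]],
                   scale_thickness(plt[[rx]][[i]], brx$vmin, brx$vmax,
                                   brx$hmax))
    }
  }
})

test_that("constant-valued PLT data renders identical frames", {
  m <- kinetic_model("v1: A => B", initial = c(A = 1),
                     parameters = c(kf_v1 = 1))
  plt <- plt_data(0:4, matrix(1, 5, 2, dimnames = list(NULL, c("A", "B"))),
                  matrix(0.5, 5, 1, dimnames = list(NULL, "v1")))
  map <- auto_layout(stoichiometric_matrix(m$reactions), "arrows")
  frames <- render_frames(map, NULL, plt)
  # identical geometry everywhere; images differ only in the progress bar,
  # so compare with the progress strip blanked out
  strip <- function(img) img[seq_len(dim(img)[1] - 40), , ]
  for (i in 2:5) {
    expect_identical(frames[[i]]$radii, frames[[1]]$radii)
    expect_identical(strip(frames[[i]]$image), strip(frames[[1]]$image))
  }
})

test_that("a species ramping across its scale renders a linear radius sequence", {
  n <- 21
  conc <- cbind(A = seq(0, 2, length.out = n), B = rep(1, n))
  flux <- matrix(0.3, n, 1, dimnames = list(NULL, "v1"))
  plt <- plt_data(seq_len(n), conc, flux)
  map <- auto_layout(stoichiometric_matrix(
    parse_reaction_list("v1: A => B")), "arrows")
  b <- animation_bindings(
    tibble::tibble(id = c("A", "B"), cmin = 0, cmax = 2, rmax = 16),
    tibble::tibble(id = "v1", vmin = 0, vmax = 1, hmax = 6,
                   style = "arrow_thickness"))
  frames <- render_frames(map, b, plt)
  r <- vapply(frames, function(f) f$radii[["A"]], 0)
  fit <- lm(r ~ seq_len(n))
  expect_equal(unname(coef(fit)[2]), 16 / (n - 1) * (2 / 2), tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("unmatched map titles are listed in the error", {
  plt <- mini_tc_plt(3)
  map <- auto_layout(fixture_model("mini_krebs")$S, "arrows")
  map$nodes$id[1] <- "Zeta"; map$nodes$label[1] <- "Zeta"
  expect_error(render_frames(map, NULL, plt), "Zeta")
})

test_that("bars mode animates heights from both concentrations and rates", {
  plt <- mini_tc_plt(5)
  m <- fixture_model("mini_krebs")
  map <- auto_layout(m$S, "bars")
  frames <- render_frames(map, NULL, plt)
  expect_length(frames, 5)
  hts <- frames[[3]]$heights
  expect_named(hts, map$bars$id, ignore.order = TRUE)
  expect_true(all(hts >= 0 & hts <= map$bars$max_height + 1e-9))
})

test_that("AVI export decodes back to the same frames and metadata", {
  plt <- mini_tc_plt(10)
  m <- fixture_model("mini_krebs")
  map <- auto_layout(m$S, "arrows")
  frames <- render_frames(map, NULL, plt)
  f <- withr::local_tempfile(fileext = ".avi")
  export_video(frames, f, fps = 5)
  info <- read_avi(f, frames = TRUE)
  expect_equal(info$n_frames, 10)        # 10 frames at 5 fps: 2 seconds
  expect_equal(info$n_chunks, 10)
  expect_equal(info$fps, 5)
  expect_equal(info$width, dim(frames[[1]]$image)[2])
  expect_equal(info$height, dim(frames[[1]]$image)[1])
  # pixel data round-trips within 8-bit quantization
  for (i in c(1, 10))
    expect_lt(max(abs(info$images[[i]] - frames[[i]]$image)), 1 / 255)

  # single frame edge case
  f1 <- withr::local_tempfile(fileext = ".avi")
  export_video(frames[1], f1, fps = 10)
  one <- read_avi(f1)
  expect_equal(one$n_frames, 1)
  expect_equal(one$n_chunks, 1)
})
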