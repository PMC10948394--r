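test_that("intermodes threshold is the midpoint of two spike modes", {
  px <- matrix(c(rep(10, 800), rep(200, 800)), 40, 40)
  expect_equal(intermodes_threshold(px), 105, tolerance = 1e-9)
  # shift covariance: adding a constant shifts the threshold by it
  expect_equal(intermodes_threshold(px + 17), 122, tolerance = 1e-9)
})

test_that("intermodes matches the exhaustive smoothing oracle on mixtures", {
  set.seed(11)
  for (rep in 1:5) {
    v <- c(rnorm(10000, 30, 10), rnorm(10000, 180, 10))
    v <- pmin(pmax(round(v), 0), 255)
    px <- matrix(v, 200, 100)
    thr <- intermodes_threshold(px)
    expect_gte(thr, 90); expect_lte(thr, 120)
    expect_equal(thr, oracle_intermodes(px), tolerance = 1e-12)
  }
})

test_that("non-bimodal histograms error or fall back as configured", {
  px <- matrix(42, 40, 40)
  expect_error(intermodes_threshold(px), "constant image")
  expect_error(intermodes_threshold(px, on_unimodal = "otsu_fallback"),
               "constant")
  # unimodal but non-constant: error policy names the condition
  uni <- matrix(round(rnorm(1600, 100, 3)), 40, 40)
  got <- tryCatch(intermodes_threshold(uni), error = function(e) e)
  if (inherits(got, "error")) {
    expect_match(conditionMessage(got), "unimodal|iteration")
    thr <- intermodes_threshold(uni, on_unimodal = "otsu_fallback")
    expect_true(is.finite(thr))
  } else {
    expect_true(is.finite(got))
  }
})

test_that("phansalkar threshold reproduces hand-computed plateau cases", {
  zero <- matrix(0, 40, 40)
  expect_false(any(phansalkar_threshold(zero, bit_depth = 8L)))

  half <- matrix(127.5, 40, 40)  # exactly 0.5 normalized
  mask <- phansalkar_threshold(half, bit_depth = 8L)
  # t = 0.5 * (1 + 2 exp(-5) - 0.25) ~ 0.3817 < 0.5 everywhere
  expect_true(all(mask))

  two <- matrix(0.2 * 255, 48, 96)
  two[, 49:96] <- 0.8 * 255
  mask2 <- phansalkar_threshold(two, bit_depth = 8L)
  # plateau interiors (windows fully inside): left t ~ 0.20413 -> background,
  # right t ~ 0.60054 -> foreground
  expect_false(any(mask2[, 1:30]))
  expect_true(all(mask2[, 67:96]))

  expect_error(phansalkar_threshold(matrix(0, 20, 20), radius = 15),
               "radius")
})

test_that("phansalkar equals naive per-pixel evaluation on small images", {
  set.seed(21)
  fixtures <- list(
    matrix(sample(0:255, 24 * 24, replace = TRUE), 24, 24),
    {m <- matrix(10, 64, 64); m[20:40, 20:40] <- 200; m},
    matrix(round(100 + 80 * sin(outer(1:48, 1:48, "+") / 5)), 48, 48)
  )
  for (px in fixtures) {
    for (rad in c(3L, 7L)) {
      got <- phansalkar_threshold(px, radius = rad, bit_depth = 8L)
      want <- oracle_phansalkar(px, radius = rad, bit_depth = 8L)
      expect_identical(got, want)
    }
  }
})

test_that("mask combination keeps whole seeded components", {
  local <- matrix(FALSE, 40, 40)
  local[5:12, 5:12] <- TRUE      # component A
  local[25:32, 25:32] <- TRUE    # component B
  global <- matrix(FALSE, 40, 40)
  global[5, 5] <- TRUE           # overlaps A by exactly one pixel

  seeded <- combine_masks(global, local)
  expect_equal(sum(seeded[5:12, 5:12]), 64)   # retained whole
  expect_false(any(seeded[25:32, 25:32]))     # unseeded: removed
  inter <- combine_masks(global, local, mode = "intersection")
  expect_identical(inter, global & local)     # clipped to 1 px
  expect_equal(sum(inter), 1)

  # component fully inside global is retained by both modes
  global2 <- matrix(FALSE, 40, 40); global2[5:12, 5:12] <- TRUE
  expect_equal(sum(combine_masks(global2, local)), 64)
  expect_equal(sum(combine_masks(global2, local, "intersection")), 64)

  expect_error(combine_masks(global, matrix(FALSE, 10, 10)), "shape")
})

test_that("component labeling honours connectivity and the area floor", {
  m <- matrix(FALSE, 20, 20)
  m[3, 3] <- TRUE; m[4, 4] <- TRUE  # diagonal pair
  lab8 <- label_components(m, 8, min_area_px = 0L)
  lab4 <- label_components(m, 4, min_area_px = 0L)
  expect_equal(attr(lab8, "n_labels"), 1L)
  expect_equal(attr(lab4, "n_labels"), 2L)
  # both dropped by the default 10 px floor
  expect_equal(attr(label_components(m, 8), "n_labels"), 0L)

  sq <- matrix(FALSE, 30, 30); sq[10:19, 10:19] <- TRUE
  expect_equal(attr(label_components(sq), "n_labels"), 1L)
  # a component whose area equals the floor is kept
  ten <- matrix(FALSE, 20, 20); ten[5:9, 5:6] <- TRUE
  expect_equal(attr(label_components(ten, min_area_px = 10L), "n_labels"), 1L)
})

test_that("labeling matches brute-force flood fill on random masks", {
  set.seed(33)
  for (conn in c(4L, 8L)) {
    for (rep in 1:4) {
      m <- matrix(runif(30 * 30) < 0.35, 30, 30)
      lab <- label_components(m, connectivity = conn, min_area_px = 0L)
      want <- oracle_component_pixel_sets(m, connectivity = conn)
      expect_equal(attr(lab, "n_labels"), length(want))
      got_sets <- split(which(lab > 0), lab[lab > 0])
      got_sets <- unname(lapply(got_sets, sort))
      # permutation-invariant comparison of pixel sets
      key <- function(s) paste(s, collapse = ",")
      expect_setequal(vapply(got_sets, key, ""), vapply(want, key, ""))
    }
  }
})
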