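test_that("empty scenes are pure background and generation is deterministic", {
  spec <- scene_spec(n_nuclei = 0L, n_nets = 0L, n_fragments = 0L,
                     n_doublets = 0L, rng_seed = 5L)
  g <- generate_field(spec)
  expect_equal(nrow(g$truth$objects), 0)
  expect_true(all(g$truth$labels == 0L))
  expect_lt(max(g$field$pixels), spec$background_level + 8 * spec$noise_sd)

  spec2 <- scene_spec(rng_seed = 9L)
  a <- generate_field(spec2)
  b <- generate_field(spec2)
  expect_identical(a$field$pixels, b$field$pixels)
  expect_identical(a$truth$labels, b$truth$labels)
  # a different seed changes the scene
  spec3 <- scene_spec(rng_seed = 10L)
  expect_false(identical(generate_field(spec3)$field$pixels, a$field$pixels))
})

test_that("ground-truth composition matches the scene specification", {
  spec <- scene_spec(n_nuclei = 20L, n_nets = 5L, n_fragments = 3L,
                     n_doublets = 2L, rng_seed = 13L)
  g <- generate_field(spec)
  counts <- table(g$truth$objects$class)
  expect_equal(counts[["nucleus"]], 20)
  expect_equal(counts[["net"]], 5)
  expect_equal(counts[["fragment"]], 3)
  expect_equal(counts[["doublet"]], 2)
  expect_equal(attr(g$truth, "net_fraction"), 0.2)
  # labels are disjoint and only cover listed objects
  expect_setequal(unique(as.integer(g$truth$labels[g$truth$labels > 0])),
                  g$truth$objects$object_id)
})

test_that("rendered objects conserve DNA in nucleus-equivalents", {
  for (sd in 1:5) {
    g <- generate_field(scene_spec(rng_seed = sd))
    obj <- g$truth$objects
    nets <- obj$nucleus_equivalents[obj$class == "net"]
    doublets <- obj$nucleus_equivalents[obj$class == "doublet"]
    expect_true(all(nets >= 0.8 & nets <= 1.2))
    expect_true(all(doublets >= 1.8 & doublets <= 2.2))
    # fragments carry a small fraction of a nucleus
    frags <- obj$nucleus_equivalents[obj$class == "fragment"]
    expect_true(all(frags < 0.2))
  }
})

test_that("scene fraction adjustment preserves the total cell count", {
  spec <- scene_spec()
  for (fr in c(0, 0.2, 0.5)) {
    s <- scene_spec_for_fraction(spec, fr)
    expect_equal(s$n_nets + s$n_nuclei, spec$n_nets + spec$n_nuclei)
    expect_equal(s$n_nets / (s$n_nets + s$n_nuclei), fr)
  }
  expect_error(scene_spec_for_fraction(spec, 1.0))
})

test_that("overcrowded scenes fail with a class-naming error", {
  spec <- scene_spec(shape = c(128L, 128L), n_nets = 30L,
                     placement_attempts = 25L, rng_seed = 3L)
  expect_error(generate_field(spec), "overcrowded.*net")
})

test_that("evaluation against truth matches identity and split detections", {
  spec <- scene_spec(rng_seed = 17L)
  g <- generate_field(spec)
  truth <- g$truth
  # detections identical to the truth labels: diagonal confusion, zero error
  calls <- truth$objects |>
    dplyr::transmute(roi_id = .data$object_id,
                     call = dplyr::case_when(
                       class == "net" ~ "net",
                       class == "nucleus" ~ "nucleus",
                       class == "doublet" ~ "eliminated_multiple",
                       class == "fragment" ~ "eliminated_fragment"))
  ev <- evaluate_against_truth(calls, truth$labels, truth)
  expect_equal(nrow(ev$matches), nrow(truth$objects))
  expect_true(all(ev$matches$iou == 1))
  expect_equal(ev$net_percent_error, 0)
  off_diag <- ev$confusion$n[ev$confusion$class == "nucleus" &
                               ev$confusion$call != "nucleus"]
  expect_equal(sum(off_diag), 0)

  # split one truth nucleus into two detections: one match + one unmatched
  nuc_id <- truth$objects$object_id[truth$objects$class == "nucleus"][1]
  det <- truth$labels
  px <- which(det == nuc_id)
  top <- px[seq_len(floor(length(px) / 4))]
  new_id <- max(det) + 1L
  det[top] <- new_id
  calls2 <- dplyr::bind_rows(calls,
                             tibble::tibble(roi_id = new_id, call = "nucleus"))
  ev2 <- evaluate_against_truth(calls2, det, truth, iou_min = 0.5)
  expect_true(nuc_id %in% ev2$matches$truth_id)
  expect_false(new_id %in% ev2$matches$roi_id)
  unmatched_det <- ev2$confusion$n[ev2$confusion$class == "unmatched"]
  expect_equal(sum(unmatched_det), 1)
  expect_error(evaluate_against_truth(calls, truth$labels[1:100, 1:100], truth),
               "shape")
})

test_that("simulate_study writes a coherent image/manifest/truth triplet", {
  dir <- withr::local_tempdir()
  slides <- tibble::tibble(slide_id = c("P1", "C1"),
                           condition = "spontaneous",
                           group = c("patient", "control"),
                           net_fraction = c(0.2, 0))
  out <- simulate_study(dir, slides = slides, n_fields = 2L, seed = 8L)
  expect_equal(nrow(out$manifest), 4)
  expect_true(all(file.exists(out$manifest$field_path)))
  m <- load_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 4)
  truth <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE)
  expect_true(all(c("object_id", "class", "area_px", "integrated_intensity")
                  %in% names(truth)))
  # fields are reproducible piecewise from (seed, slide, field)
  f1 <- load_field(out$manifest$field_path[1])
  spec <- scene_spec_for_fraction(scene_spec(), 0.2)
  spec$rng_seed <- netquant:::field_seed(8L, 1L, 1L)
  again <- generate_field(spec)
  expect_identical(f1$pixels, again$field$pixels)
})
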