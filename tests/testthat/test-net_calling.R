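test_that("reference area fixed point matches brute-force expectations", {
  # all equal: reference is that area, no candidates
  r <- reference_area(rep(100, 10))
  expect_equal(r$reference_area, 100)
  expect_length(r$net_candidate_ids, 0)

  # ten nuclei plus one large object: median resists inflation
  r2 <- reference_area(c(rep(100, 10), 600))
  expect_equal(r2$reference_area, 100)
  expect_equal(r2$net_candidate_ids, 11L)

  # sparse two-ROI field: median straddles and under-calls (documented)
  r3 <- reference_area(c(100, 430))
  expect_equal(r3$reference_area, 265)
  expect_length(r3$net_candidate_ids, 0)

  expect_error(reference_area(numeric(0)), "no ROIs")
})

test_that("reference area candidate set grows monotonically to a fixed point", {
  set.seed(41)
  for (rep in 1:20) {
    areas <- c(round(rnorm(15, 120, 15)), round(runif(3, 500, 1500)))
    r <- reference_area(areas)
    cand <- areas / r$reference_area >= 4.30
    # returned candidates are exactly the ROIs at/above the cutoff w.r.t.
    # the final reference (self-consistency of the fixed point)
    expect_setequal(r$net_candidate_ids, which(cand))
    expect_equal(r$reference_area, median(areas[!cand]))
  }
})

test_that("classification cutoffs are inclusive/strict exactly as specified", {
  cfg <- net_config()
  # areas chosen so reference = 100; RID tuned per case
  base_rid <- 1000
  m <- make_measurements(
    area = c(rep(100, 9), 430),
    rid = c(rep(base_rid, 9), base_rid)
  )
  calls <- classify_rois(m, cfg)
  # relative_area exactly 4.30 -> net (cutoff inclusive)
  expect_equal(calls$call[10], "net")
  expect_equal(calls$relative_area[10], 4.30)

  # relative_dna 1.20 stays a nucleus, 1.21 is eliminated (strict >)
  m2 <- make_measurements(
    area = rep(100, 11),
    rid = c(rep(1000, 9), 1200, 1210)
  )
  c2 <- classify_rois(m2, cfg)
  expect_equal(c2$relative_dna[10], 1.20)
  expect_equal(c2$call[10], "nucleus")
  expect_equal(c2$call[11], "eliminated_multiple")

  # relative_dna 0.49 -> fragment (strict <.5); 0.50 retained
  m3 <- make_measurements(area = rep(100, 11),
                          rid = c(rep(1000, 9), 490, 500))
  c3 <- classify_rois(m3, cfg)
  expect_equal(c3$call[10], "eliminated_fragment")
  expect_equal(c3$call[11], "nucleus")

  # plain nucleus
  expect_equal(classify_rois(make_measurements(rep(100, 5)), cfg)$call,
               rep("nucleus", 5))
})

test_that("border exclusion precedes everything and empty fields propagate", {
  m <- make_measurements(c(100, 100, 600), border = c(TRUE, FALSE, FALSE))
  calls <- classify_rois(m)
  expect_equal(calls$call[1], "eliminated_border")
  c0 <- classify_rois(make_measurements(integer(0)))
  expect_equal(nrow(c0), 0)
  # all-border field yields no retained calls, not an error
  mb <- make_measurements(c(100, 100), border = TRUE)
  expect_equal(classify_rois(mb)$call, rep("eliminated_border", 2))
})

test_that("every ROI receives exactly one call (partition property)", {
  set.seed(43)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    m <- make_measurements(
      area = round(runif(n, 20, 1500)),
      rid = round(runif(n, 100, 5000)),
      border = runif(n) < 0.15
    )
    calls <- classify_rois(m)
    expect_false(any(is.na(calls$call)))
    counts <- table(calls$call)
    expect_equal(sum(counts), n)
    expect_true(all(names(counts) %in%
      c("nucleus", "net", "eliminated_fragment", "eliminated_multiple",
        "eliminated_border")))
  }
})

test_that("raising the NET cutoff never increases the NET count", {
  set.seed(47)
  m <- make_measurements(area = c(round(rnorm(20, 100, 12)),
                                  round(runif(6, 300, 1200))))
  cutoffs <- c(2, 3, 4.3, 6, 10)
  nets <- vapply(cutoffs, function(k) {
    sum(classify_rois(m, net_config(net_area_cutoff = k))$call == "net")
  }, numeric(1))
  expect_true(all(diff(nets) <= 0))
})

test_that("calls are invariant to intensity scaling", {
  set.seed(53)
  m <- make_measurements(area = round(runif(25, 50, 900)),
                         rid = round(runif(25, 200, 9000)))
  base <- classify_rois(m)$call
  for (c_scale in c(0.01, 3.7, 1000)) {
    ms <- m
    ms$raw_integrated_density <- ms$raw_integrated_density * c_scale
    ms$min_brightness <- ms$min_brightness * c_scale
    ms$max_brightness <- ms$max_brightness * c_scale
    expect_identical(classify_rois(ms)$call, base)
  }
})

test_that("field summaries count calls and average retained DNA", {
  m <- make_measurements(area = c(rep(100, 8), 500, 500, 100),
                         rid = c(rep(1000, 8), 1000, 1000, 400))
  calls <- classify_rois(m)
  fs <- field_summary(calls)
  expect_equal(fs$n_nets, 2L)
  expect_equal(fs$n_retained, 10L)
  expect_equal(fs$n_fragment, 1L)
  expect_equal(fs$n_retained, fs$n_nets + fs$n_nuclei)
  retained_rid <- calls$raw_integrated_density[calls$call %in% c("net", "nucleus")]
  expect_equal(fs$average_cellular_dna, mean(retained_rid))

  empty <- classify_rois(make_measurements(integer(0)))
  fe <- field_summary(empty)
  expect_equal(fe$n_retained, 0L)
  expect_true(is.na(fe$average_cellular_dna))
})

test_that("slide pooling divides total NETs by total neutrophils", {
  f <- tibble::tibble(slide_id = "S", condition = "pma", group = "g",
                      field_index = 1:2, n_retained = c(10L, 10L),
                      n_nets = c(2L, 3L), n_nuclei = c(8L, 7L),
                      n_fragment = 0L, n_multiple = 0L, n_border = 0L,
                      reference_area = 100, average_cellular_dna = 1000)
  s <- slide_summary(f)
  expect_equal(s$net_percent, 25.0)
  expect_equal(s$total_retained, 20L)

  single <- f[1, ]; single$n_nets <- 0L; single$n_retained <- 50L
  expect_equal(slide_summary(single)$net_percent, 0.0)

  # invariance to field order
  expect_equal(slide_summary(f[2:1, ])$net_percent, 25.0)

  zero <- f[1, ]; zero$n_retained <- 0L; zero$n_nets <- 0L
  expect_true(is.na(slide_summary(zero)$net_percent))
  expect_error(slide_summary(f[0, ]))
})

test_that("configuration validates its cutoff ordering and YAML round-trip", {
  expect_error(net_config(net_area_cutoff = 1.0), "cutoffs")
  expect_error(net_config(lower_elim_cutoff = 0), "cutoffs")
  expect_error(net_config(segmentation = list(bogus = 1)), "unknown")
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- net_config(net_area_cutoff = 5, segmentation = list(radius = 9L))
  write_config_snapshot(cfg, path)
  y <- yaml::read_yaml(path)
  expect_equal(y$net_area_cutoff, 5)
  expect_equal(y$segmentation$radius, 9L)
  cfg2 <- read_net_config(path)
  expect_equal(cfg2$net_area_cutoff, 5)
  expect_equal(cfg2$segmentation$radius, 9L)
})
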