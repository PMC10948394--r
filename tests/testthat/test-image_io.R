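test_that("grayscale PNG and TIFF load with native intensities", {
  px <- matrix(sample(0:255, 40 * 40, replace = TRUE), 40, 40)
  png_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(px / 255, png_path)
  f <- load_field(png_path)
  expect_s3_class(f, "net_field")
  expect_equal(f$bit_depth, 8L)
  expect_equal(f$pixels, px, ignore_attr = TRUE)

  px16 <- matrix(1000, 64, 64)
  tif_path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(px16 / 65535, tif_path, bits.per.sample = 16L)
  g <- load_field(tif_path)
  expect_equal(g$bit_depth, 16L)
  expect_true(all(g$pixels == 1000))
})

test_that("loading is idempotent and preserves total intensity", {
  px <- matrix(sample(0:65535, 48 * 48, replace = TRUE), 48, 48)
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L)
  f1 <- load_field(path); f2 <- load_field(path)
  expect_identical(f1$pixels, f2$pixels)
  # independent reader: raw tiff values
  raw <- tiff::readTIFF(path, as.is = TRUE)
  expect_equal(sum(f1$pixels), sum(raw))
})

test_that("RGB input takes the blue channel by default, others on request", {
  arr <- array(0, dim = c(40, 40, 3))
  arr[6:15, 6:15, 3] <- 200 / 255  # bright blue square
  arr[20:29, 20:29, 1] <- 90 / 255 # red square (must be ignored)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, path)
  f <- load_field(path)
  # independent slice through another reader
  direct <- round(png::readPNG(path)[, , 3] * 255)
  expect_equal(f$pixels, direct, ignore_attr = TRUE)
  expect_equal(sum(f$pixels > 0), 100)
  r <- load_field(path, channel = "red")
  expect_equal(sum(r$pixels > 0), 100)
  expect_equal(max(r$pixels), 90)
  expect_error(load_field(path, channel = "gray"), "channel")
})

test_that("malformed inputs are rejected with informative errors", {
  expect_error(load_field("does-not-exist.png"), "cannot read")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines("nope", path)
  expect_error(load_field(path), "unsupported format")
  expect_error(net_field(matrix(0, 8, 8)), "32 x 32")
  expect_error(net_field(matrix(-1, 40, 40)), "intensities")
})

test_that("manifest loads, orders, warns on extras and rejects duplicates", {
  dir <- withr::local_tempdir()
  img <- matrix(0:99 * 650, 40, 40)
  imgs <- character(0)
  rows <- list()
  for (s in c("A", "B")) for (cc in c("spontaneous", "ecoli", "pma")) {
    for (f in 1:10) {
      p <- file.path(dir, sprintf("%s_%s_%d.tif", s, cc, f))
      tiff::writeTIFF(img / 65535, p, bits.per.sample = 16L)
      rows[[length(rows) + 1]] <- data.frame(
        slide_id = s, condition = cc, group = "g", field_path = p,
        field_index = f)
    }
  }
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE)
  m <- load_manifest(path)
  expect_equal(nrow(m), 60)
  expect_equal(unique(m$slide_id), c("A", "B"))

  man2 <- man; man2$comment <- "x"
  write.csv(man2, path, row.names = FALSE)
  expect_warning(load_manifest(path), "unknown manifest column")

  man3 <- rbind(man, man[1, ])
  write.csv(man3, path, row.names = FALSE)
  expect_error(load_manifest(path), "duplicate")

  write.csv(man[, c("slide_id", "condition", "field_path")], path,
            row.names = FALSE)
  expect_error(load_manifest(path), "missing column")
})

test_that("result tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  slides <- tibble::tibble(slide_id = "S", condition = "pma", group = "g",
                           n_fields = 3L, total_retained = 31L,
                           total_nets = 7L, net_percent = 100 * 7 / 31,
                           manual_override = NA_real_,
                           final_net_percent = 100 * 7 / 31)
  paths <- write_results(list(rois = NULL, fields = NULL, slides = slides), dir)
  back <- readr::read_csv(paths[["slides"]], show_col_types = FALSE)
  expect_equal(back$net_percent, slides$net_percent, tolerance = 1e-7)
  # empty tables still carry header rows
  rois <- readr::read_csv(paths[["rois"]], show_col_types = FALSE)
  expect_equal(nrow(rois), 0)
  expect_equal(names(rois)[1:4],
               c("slide_id", "condition", "field_index", "roi_id"))
})
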