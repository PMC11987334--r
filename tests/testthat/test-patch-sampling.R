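test_that("patch side matches the area/calibration arithmetic", {
  sl <- render_biopsy_slide(0.5, mpp = 2, height_px = 512, width_px = 640,
                            seed = 3, min_patch_px = 200)
  ps <- sample_patches(sl, sl$mask, n = 10, area_mm2 = 0.16, seed = 17)
  # sqrt(0.16 mm^2) = 400 um = 200 px at 2 um/px
  expect_true(all(ps$patches$side_px == 200L))
  expect_equal(ps$n, 10)
})

test_that("every sampled patch footprint is dermis-only", {
  sl <- render_biopsy_slide(0.6, mpp = 2, height_px = 400, width_px = 520,
                            seed = 5, min_patch_px = 100)
  ps <- sample_patches(sl, sl$mask, n = 100, area_mm2 = 0.04, seed = 21)
  for (i in seq_len(ps$n)) {
    r <- ps$patches$row0[i]; c <- ps$patches$col0[i]; s <- ps$patches$side_px[i]
    expect_true(all(sl$mask[(r + 1):(r + s), (c + 1):(c + s)] == 2L))
  }
})

test_that("sampling is deterministic per seed", {
  sl <- render_biopsy_slide(0.5, mpp = 2, height_px = 400, width_px = 520,
                            seed = 5, min_patch_px = 100)
  a <- sample_patches(sl, sl$mask, n = 50, area_mm2 = 0.04, seed = 7)
  b <- sample_patches(sl, sl$mask, n = 50, area_mm2 = 0.04, seed = 7)
  expect_identical(a$patches, b$patches)
})

test_that("patch centers are uniform over a rectangular dermis", {
  # all-dermis 139x139 mask with side-40 patches: corners uniform on a
  # 100x100 grid; bin into a 4x4 partition and test goodness of fit
  sl <- mk_flat_slide(139, 139, mpp = 2)
  mask <- matrix(2L, 139, 139)
  ps <- sample_patches(sl, mask, n = 10000, area_mm2 = 0.0064, seed = 1)
  expect_true(all(ps$patches$side_px == 40L))
  cell <- function(v) pmin(v %/% 25L, 3L)
  counts <- table(factor(cell(ps$patches$row0), levels = 0:3),
                  factor(cell(ps$patches$col0), levels = 0:3))
  gof <- stats::chisq.test(as.vector(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("scarce dermis exhausts the draw cap with a typed error", {
  # a single valid 10x10 corner among 51x51 candidates: the rejection rate
  # exceeds the 1000 * n draw cap almost surely
  sl <- mk_flat_slide(60, 60, mpp = 2)
  mask <- matrix(0L, 60, 60)
  mask[1:10, 1:10] <- 2L
  err <- expect_error(sample_patches(sl, mask, n = 10, area_mm2 = 0.0004,
                                     seed = 1),
                      class = "sampling_exhausted_error")
  expect_match(conditionMessage(err), "of 10 patches placed")
})

test_that("fully fragmented dermis (no valid footprint) is a no-dermis error", {
  sl <- mk_flat_slide(60, 60, mpp = 2)
  mask <- matrix(0L, 60, 60)
  mask[seq(1, 60, by = 2), ] <- 2L           # dermis stripes 1 px tall
  expect_error(sample_patches(sl, mask, n = 2, area_mm2 = 0.0004, seed = 1),
               class = "no_dermis_error")
})

test_that("an all-background mask yields a no-dermis error", {
  sl <- mk_flat_slide(60, 60, mpp = 2)
  expect_error(sample_patches(sl, matrix(0L, 60, 60), n = 2,
                              area_mm2 = 0.0004, seed = 1),
               class = "no_dermis_error")
})
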