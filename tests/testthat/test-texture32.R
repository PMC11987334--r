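test_that("a constant patch zeroes dispersion, gradient and contrast features", {
  f <- texture32_features(array(0.5, c(32, 32, 3)))
  expect_length(f, 32)
  expect_equal(unname(f[c("collagen_sd", "counterstain_sd",
                          "hematoxylin_sd")]), c(0, 0, 0))
  expect_equal(unname(f[grep("gradmag", names(f))]), rep(0, 6))
  expect_equal(unname(f[c("glcm_contrast_01", "glcm_contrast_10")]), c(0, 0))
  expect_equal(unname(f[c("glcm_energy_01", "glcm_energy_10")]), c(1, 1))
})

test_that("a pure collagen-color patch saturates the collagen area fraction", {
  p <- array(rep(c(0.25, 0.35, 0.75), each = 24 * 24), c(24, 24, 3))
  expect_equal(unname(texture32_features(p)[["collagen_area_fraction"]]), 1)
})

test_that("GLCM features equal a brute-force co-occurrence tally", {
  glcm_brute <- function(gray, dr, dc, levels = 16L) {
    q <- pmin(pmax(floor(gray * levels), 0), levels - 1L) + 1L
    P <- matrix(0, levels, levels)
    for (r in seq_len(nrow(q) - dr)) for (cc in seq_len(ncol(q) - dc)) {
      P[q[r, cc], q[r + dr, cc + dc]] <- P[q[r, cc], q[r + dr, cc + dc]] + 1
    }
    P <- P / sum(P)
    i <- row(P); j <- col(P)
    mi <- sum(i * P); mj <- sum(j * P)
    si <- sqrt(sum((i - mi)^2 * P)); sj <- sqrt(sum((j - mj)^2 * P))
    c(contrast = sum(P * (i - j)^2),
      homogeneity = sum(P / (1 + (i - j)^2)),
      energy = sum(P^2),
      correlation = if (si < 1e-12 || sj < 1e-12) 0 else
        sum((i - mi) * (j - mj) * P) / (si * sj))
  }
  set.seed(3)
  for (rep in 1:5) {
    g <- matrix(runif(24 * 24), 24, 24)
    expect_equal(fibroscore:::glcm_stats(g, 0L, 1L), glcm_brute(g, 0L, 1L),
                 tolerance = 1e-12)
    expect_equal(fibroscore:::glcm_stats(g, 1L, 0L), glcm_brute(g, 1L, 0L),
                 tolerance = 1e-12)
  }
  # 2-px-period checkerboard, the classical high-contrast case
  cb <- outer(1:16, 1:16, function(r, c)
    ifelse(((r - 1) %/% 2 + (c - 1) %/% 2) %% 2 == 0, 0.2, 0.8))
  expect_equal(fibroscore:::glcm_stats(cb, 0L, 1L), glcm_brute(cb, 0L, 1L),
               tolerance = 1e-12)
})

test_that("the collagen-area-fraction feature tracks planted severity", {
  grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  frac <- vapply(grid, function(s) {
    sl <- render_biopsy_slide(s, mpp = 2, height_px = 300, width_px = 380,
                              seed = 11, min_patch_px = 80)
    ps <- sample_patches(sl, sl$mask, n = 5, area_mm2 = 0.0256, seed = 4)
    q <- extract_qif(sl, ps, make_backend("texture32"))
    mean(q$values[, "collagen_area_fraction"])
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("feature extraction is deterministic and shape-checked", {
  sl <- render_biopsy_slide(0.5, mpp = 2, height_px = 300, width_px = 380,
                            seed = 2, min_patch_px = 80)
  ps <- sample_patches(sl, sl$mask, n = 8, area_mm2 = 0.01, seed = 6)
  be <- make_backend("texture32")
  a <- extract_qif(sl, ps, be)
  b <- extract_qif(sl, ps, be)
  expect_identical(a$values, b$values)
  expect_equal(dim(a$values), c(8L, 32L))
  expect_true(all(is.finite(a$values)))
  expect_error(texture32_features(array(0.5, c(10, 12, 3))),
               class = "geometry_error")
})

test_that("out-of-bounds patches are rejected with a geometry error", {
  sl <- mk_flat_slide(50, 50)
  bad <- structure(list(biopsy_id = "b", n = 1L, side_px = 30L,
                        area_mm2 = 0.0036, seed = 1L,
                        patches = data.frame(row0 = 40L, col0 = 0L,
                                             side_px = 30L)),
                   class = "patch_set")
  expect_error(extract_qif(sl, bad, make_backend("texture32")),
               class = "geometry_error")
})
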