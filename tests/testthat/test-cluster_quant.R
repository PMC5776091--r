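## brute-force grayscale opening (erosion then dilation with a disc),
## the independent oracle for the top-hat
brute_tophat <- function(img, r_px) {
  offs <- expand.grid(dr = -r_px:r_px, dc = -r_px:r_px)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r_px^2, ]
  H <- nrow(img); W <- ncol(img)
  shift_apply <- function(x, fun, pad) {
    out <- matrix(pad, H, W)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      rr <- i + offs$dr; cc <- j + offs$dc
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      out[i, j] <- fun(x[cbind(rr[ok], cc[ok])])
    }
    out
  }
  er <- shift_apply(img, min, Inf)
  op <- shift_apply(er, max, -Inf)
  img - op
}

test_that("top-hat homogenization matches a brute-force oracle", {
  set.seed(4)
  img <- matrix(10, 20, 24)
  img[8, 12] <- 60; img[8, 13] <- 55   # 2-px bright spot
  th <- homogenize_background(img, radius = 0.5, pixel_size = 0.1)
  oracle <- brute_tophat(img, 5L)
  ## spot preserved within 5%, background flattened to ~0
  expect_lt(abs(th[8, 12] - oracle[8, 12]) / oracle[8, 12], 0.05)
  expect_lt(max(th[1:5, 1:5]), 1e-9)
  ## constant image maps to zero
  expect_equal(max(abs(homogenize_background(matrix(7, 15, 15), 0.5, 0.1))),
               0)
  ## invariant to adding a constant
  th2 <- homogenize_background(img + 100, 0.5, 0.1)
  expect_equal(th2, th, tolerance = 1e-9)
  expect_error(homogenize_background(img, radius = 0), "positive")
  expect_true(all(th >= 0))
})

test_that("focus detection obeys its contract on rendered cells", {
  cfg <- sim_config(seed = 1)
  ## uniform noise-free cell: nothing above threshold
  st <- list(cx = 3, cy = 1.2, length = 3.5, width = 1, budget = 1000,
             cluster_frac = 0, sigma = 0.2)
  p <- render_cell_frame(st, cfg, 1:24, 1:60)
  expect_equal(nrow(detect_clusters(p$mask, p$fluor, 0.1)), 0L)
  expect_error(detect_clusters(matrix(FALSE, 4, 4), matrix(0, 4, 4), 0.1),
               "empty mask")
  ## one focus detected, area within 30% of the true half-max footprint
  st$cluster_frac <- 0.5; st$cluster_x <- 3 - 1.4; st$cluster_y <- 1.2
  p2 <- render_cell_frame(st, cfg, 1:24, 1:60)
  det <- detect_clusters(p2$mask, p2$fluor, 0.1)
  expect_equal(sum(det$primary), 1L)
  truth_area <- 2 * pi * 0.2^2   # 1/e footprint of the spot
  expect_lt(abs(det$area_um2[det$primary] - truth_area) / truth_area, 0.3)
  ## detection count is monotone non-increasing in k_sigma
  img_noisy <- p2$fluor + matrix(rnorm(length(p2$fluor), 0, 0.3),
                                 nrow(p2$fluor))
  counts <- vapply(c(0.5, 1, 2, 3, 5), function(k)
    nrow(detect_clusters(p2$mask, img_noisy, 0.1, k_sigma = k)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("MI and SDI follow the direct formulas and scaling laws", {
  m <- matrix(TRUE, 2, 2)
  s <- cell_intensity_stats(m, matrix(c(0, 0, 10, 10), 2))
  expect_equal(s$mi, 5)
  expect_equal(s$sdi, 5)   # population SD
  s2 <- cell_intensity_stats(m, matrix(7, 2, 2))
  expect_equal(s2$mi, 7)
  expect_equal(s2$sdi, 0)
  ## linear scaling with a multiplicative intensity rescale
  set.seed(11)
  img <- matrix(runif(16, 1, 5), 4)
  a <- cell_intensity_stats(matrix(TRUE, 4, 4), img)
  b <- cell_intensity_stats(matrix(TRUE, 4, 4), 3.5 * img)
  expect_equal(b$mi, 3.5 * a$mi)
  expect_equal(b$sdi, 3.5 * a$sdi)
})

test_that("SDI rises with the focus share and correlates with focus area", {
  sweep <- fx_fraction_sweep()
  ## strictly increasing in the budget share, noise-free
  expect_true(all(diff(sweep$fixed_sigma$sdi) > 0))
  ## MI unchanged by moving budget into the focus
  expect_lt(diff(range(sweep$fixed_sigma$mi)) / mean(sweep$fixed_sigma$mi),
            1e-9)
  ## SDI is a usable proxy for focus size across a heterogeneous sweep
  jt <- sweep$joint[!is.na(sweep$joint$area), ]
  r <- correlation(jt$area, jt$sdi, method = "pearson")
  expect_gte(r$coefficient, 0.8)
})
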