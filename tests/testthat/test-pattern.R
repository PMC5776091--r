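track_df <- function(axial, x = NULL, y = 0, present = TRUE) {
  n <- length(axial)
  data.frame(frame = seq_len(n),
             cluster_present = rep_len(present, n),
             x_um = if (is.null(x)) axial * 4 else x,
             y_um = rep_len(y, n), axial = axial)
}

test_that("pole zones are constructed and queried correctly", {
  z <- assign_pole_zones(0.25)
  expect_equal(z$pole1, c(0, 0.25))
  expect_equal(z$pole2, c(0.75, 1))
  expect_equal(z$midcell, c(0.375, 0.625))
  expect_true(polefocus:::in_zone(0.10, z$pole1))
  expect_true(polefocus:::in_zone(0.50, z$midcell))
  expect_false(polefocus:::in_zone(0.30, z$pole1) ||
               polefocus:::in_zone(0.30, z$pole2) ||
               polefocus:::in_zone(0.30, z$midcell))
  expect_error(assign_pole_zones(0.6), "pole_zone_fraction")
})

test_that("classification follows the four-way rule", {
  z <- assign_pole_zones()
  ## no detections: UC
  tr <- track_df(rep(NA_real_, 6), x = NA_real_, y = NA_real_,
                 present = FALSE)
  expect_equal(classify_pattern(tr, z)$label, "uc")
  ## fixed centroid at a pole: non-dynamic
  expect_equal(classify_pattern(track_df(rep(0.1, 6)), z)$label, "non_dyn")
  ## wandering within one pole zone: Dyn-1P
  expect_equal(classify_pattern(track_df(c(0.05, 0.2, 0.1, 0.22, 0.08)),
                                z)$label, "dyn_1p")
  ## crossing to the other pole: Dyn-OP
  expect_equal(classify_pattern(track_df(c(0.1, 0.5, 0.9, 0.2, 0.8)),
                                z)$label, "dyn_op")
  ## starting at midcell is Dyn-OP by convention
  expect_equal(classify_pattern(track_df(c(0.5, 0.55, 0.45, 0.5)),
                                z)$label, "dyn_op")
  ## short tracks are unclassifiable
  expect_true(is.na(classify_pattern(track_df(c(0.1, 0.1, 0.1)), z)$label))
  ## left-right pole flip leaves the label unchanged
  for (ax in list(c(0.1, 0.2, 0.05, 0.15, 0.2),
                  c(0.1, 0.5, 0.2, 0.1, 0.15),
                  rep(0.12, 5))) {
    a <- classify_pattern(track_df(ax), z)$label
    b <- classify_pattern(track_df(1 - ax), z)$label
    expect_identical(a, b)
  }
})

test_that("population fractions count correctly and sum to one", {
  pf <- population_fractions(c("uc", "uc", "dyn_1p", "dyn_1p"))
  expect_equal(unname(pf$fractions["uc"]), 0.5)
  expect_equal(unname(pf$fractions["dyn_1p"]), 0.5)
  expect_equal(unname(pf$fractions["non_dyn"]), 0)
  expect_equal(sum(pf$fractions), 1, tolerance = 1e-12)
  expect_equal(unname(pf$detectable), 0.5)
  ## detectable-focus fraction complements the UC fraction
  pf2 <- population_fractions(rep(c("uc", "dyn_1p", "dyn_op"),
                                  c(37, 43, 20)))
  expect_equal(unname(pf2$detectable), 0.63)
  expect_error(population_fractions(character(0)), "no labels")
})

test_that("classifier is exact on noise-free canonical tracks", {
  ## the non-Dyn and UC definitions are exact; Dyn classes must be
  ## near-perfect on clean generator-style tracks
  z <- assign_pole_zones()
  set.seed(31)
  n_ok <- 0L
  for (i in 1:50) {
    kind <- sample(c("non_dyn", "dyn_1p", "dyn_op", "uc"), 1)
    ax <- switch(kind,
                 non_dyn = rep(runif(1, 0.05, 0.12), 8) + rnorm(8, 0, 0.002),
                 dyn_1p = runif(8, 0.02, 0.28),
                 dyn_op = c(runif(4, 0.02, 0.2), runif(4, 0.45, 0.95)),
                 uc = rep(NA_real_, 8))
    tr <- if (kind == "uc")
      track_df(ax, x = NA_real_, y = NA_real_, present = FALSE)
    else track_df(ax)
    if (classify_pattern(tr, z)$label == kind) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / 50, 0.95)
})

test_that("end-to-end classification on rendered cells matches truth", {
  fx <- fx_small_pop()
  lab <- merge(fx$res$labels, fx$match, by = "cell")
  lab <- lab[!is.na(lab$label), ]
  expect_gte(nrow(lab), 49)
  expect_gte(mean(lab$label == lab$pattern), 0.9)
  ## non-Dyn and UC are exact on this noise level
  for (k in c("non_dyn", "uc")) {
    sub <- lab[lab$pattern == k, ]
    expect_gte(mean(sub$label == k), 0.99)
  }
})
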