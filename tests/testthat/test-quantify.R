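make_zone_table <- function(sums_out, sums_in, area = 1) {
  n <- length(sums_out) + length(sums_in)
  tibble::tibble(
    label = seq_len(n), area_px = area,
    centroid_row = 1, centroid_col = 1,
    mean_marker = c(sums_out, sums_in) / area,
    sum_marker = c(sums_out, sums_in),
    zone = rep(c("outside", "inside"), c(length(sums_out), length(sums_in))))
}

test_that("enrichment follows the difference-and-divide bookkeeping exactly", {
  tab <- make_zone_table(c(30, 30), c(10, 10))
  e <- rim_enrichment(tab, "marker")
  expect_equal(e$mean_outside, 30)
  expect_equal(e$mean_inside, 10)
  expect_equal(e$outside_inside_ratio, 3)
  expect_equal(e$percent_brighter, 200)
  # internal identities hold exactly
  expect_identical(e$sum_inside, e$sum_total - e$sum_outside)
  expect_identical(e$n_inside, e$n_total - e$n_outside)
  expect_equal(e$sum_total, 80); expect_equal(e$sum_outside, 60)
  expect_equal(e$mean_total, 20)
  # tidy() mirrors the object
  td <- tidy(e)
  expect_equal(td$outside_inside_ratio, 3)
  expect_equal(td$n_total, 4)
})

test_that("uniform intensity gives ratio 1 and empty zones raise errors", {
  tab <- make_zone_table(c(5, 5, 5), c(5, 5))
  e <- rim_enrichment(tab, "marker")
  expect_equal(e$outside_inside_ratio, 1)
  expect_equal(e$percent_brighter, 0)
  only_out <- make_zone_table(c(5, 5), numeric(0))
  expect_error(rim_enrichment(only_out, "marker"), "inside")
  only_in <- make_zone_table(numeric(0), c(5, 5))
  expect_error(rim_enrichment(only_in, "marker"), "outside")
  expect_error(rim_enrichment(tab, "nope"), "sum_nope")
})

test_that("enrichment is gain-invariant and offset-corrected by background", {
  withr::with_seed(4, {
    tab <- make_zone_table(runif(8, 20, 40), runif(12, 5, 15), area = 10)
    e0 <- rim_enrichment(tab, "marker")
    g <- tab; g$sum_marker <- g$sum_marker * 7; g$mean_marker <- g$mean_marker * 7
    expect_equal(rim_enrichment(g, "marker")$outside_inside_ratio,
                 e0$outside_inside_ratio)
    # an additive per-pixel offset changes the ratio ...
    off <- tab; off$sum_marker <- off$sum_marker + 3 * off$area_px
    expect_false(isTRUE(all.equal(
      rim_enrichment(off, "marker")$outside_inside_ratio,
      e0$outside_inside_ratio)))
    # ... and background subtraction restores it
    expect_equal(rim_enrichment(off, "marker", background = 3)$outside_inside_ratio,
                 e0$outside_inside_ratio)
    # relabeling invariance
    perm <- sample(nrow(tab))
    expect_equal(rim_enrichment(tab[perm, ], "marker")$outside_inside_ratio,
                 e0$outside_inside_ratio)
  })
})

test_that("condition summaries report ROI- and image-level statistics", {
  t1 <- tibble::tibble(mean_marker = rep(5, 4))
  cs <- condition_summary(list(ctrl = t1), "marker")
  expect_equal(cs$mean_roi, 5); expect_equal(cs$sd_roi, 0)
  expect_equal(cs$mean_image, 5); expect_equal(cs$sd_image, 0)
  # permuting image order leaves the summary unchanged
  t2 <- tibble::tibble(mean_marker = c(1, 2, 3))
  t3 <- tibble::tibble(mean_marker = c(7, 9))
  a <- condition_summary(list(cond = list(t2, t3)), "marker")
  b <- condition_summary(list(cond = list(t3, t2)), "marker")
  expect_equal(a$mean_roi, b$mean_roi)
  expect_equal(a$mean_image, b$mean_image)
  expect_equal(a$n_images, 2); expect_equal(a$n_rois, 5)
  # image-level mean is the mean of per-image means, not the pooled mean
  expect_equal(a$mean_image, mean(c(mean(c(1, 2, 3)), mean(c(7, 9)))))
})

test_that("positive fractions respect their thresholding rules", {
  tab <- tibble::tibble(mean_marker = c(rep(10, 70), rep(40, 30)))
  pf <- positive_fraction(tab, "marker", "otsu")
  expect_equal(pf$fraction, 0.3)
  expect_equal(pf$n_positive, 30L)
  # fixed thresholds beyond the range give 0 or 1
  expect_equal(positive_fraction(tab, "marker", "fixed", threshold = 100)$fraction, 0)
  expect_equal(positive_fraction(tab, "marker", "fixed", threshold = 1)$fraction, 1)
  # monotone non-increasing in the threshold
  fr <- vapply(c(0, 5, 15, 39, 41),
               function(t) positive_fraction(tab, "marker", "fixed",
                                             threshold = t)$fraction,
               numeric(1))
  expect_true(all(diff(fr) <= 0))
  # gmm2 agrees on a clearly bimodal sample
  withr::with_seed(8, {
    tb <- tibble::tibble(mean_marker = c(rnorm(140, 10, 1), rnorm(60, 40, 2)))
    pg <- positive_fraction(tb, "marker", "gmm2")
    expect_equal(pg$fraction, 0.3, tolerance = 0.02)
  })
  expect_error(positive_fraction(tab[1, ], "marker", "otsu"), "at least 2")
  expect_error(positive_fraction(tab, "marker", "fixed"), "threshold")
})

test_that("densitometry ratios are exact without noise and scale-invariant", {
  g <- simulate_gel(gel_spec(gel_lanes_standard(), noise_sd = 0))
  r <- densitometry_ratio(g$image, g$annotations)
  expect_equal(r$relative_intensity, c(0.5, 1, 2), tolerance = 0.01)
  # doubling the whole gel leaves ratios unchanged
  r2 <- densitometry_ratio(g$image * 2, g$annotations)
  expect_equal(r2$relative_intensity, r$relative_intensity, tolerance = 1e-6)
  # a band window with no signal integrates to 0
  ann <- g$annotations
  ann$row_lo[ann$band == "X" & ann$lane == 1] <- 10
  ann$row_hi[ann$band == "X" & ann$lane == 1] <- 30
  r3 <- densitometry_ratio(g$image, ann)
  expect_equal(r3$relative_intensity[r3$lane == 1], 0)
  # vanished control is an error
  ann2 <- g$annotations
  ann2$row_lo[ann2$control & ann2$lane == 1] <- 5
  ann2$row_hi[ann2$control & ann2$lane == 1] <- 20
  expect_error(densitometry_ratio(g$image, ann2), "control")
})

test_that("background estimation reads the off-mask median", {
  x <- matrix(10, 50, 50)
  mask <- disk(50, 50, 25, 25, 15)
  x[mask] <- 200
  expect_equal(estimate_background(x, mask), 10)
  expect_equal(estimate_background(x), stats::median(x))
})
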