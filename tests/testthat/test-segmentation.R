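test_that("median filter equals the brute-force sliding-window median", {
  withr::with_seed(1, {
    for (rep in 1:10) {
      x <- matrix(runif(256), 16, 16)
      expect_equal(median_denoise(x, 1), bf_median(x, 1), tolerance = 0)
    }
    x <- matrix(runif(144), 12, 12)
    expect_equal(median_denoise(x, 2), bf_median(x, 2))
  })
  # identity cases and hot-pixel removal
  const <- matrix(3.5, 8, 8)
  expect_identical(median_denoise(const, 1), const)
  expect_identical(median_denoise(const, 0), const)
  hot <- matrix(0, 9, 9); hot[5, 5] <- 100
  expect_equal(median_denoise(hot, 1)[5, 5], 0)
})

test_that("contrast stretch maps quantiles to the unit range", {
  x <- matrix(0:255, 16, 16)
  y <- rescale_contrast(x, 0)
  expect_equal(y, (x - min(x)) / (max(x) - min(x)))   # affine of the input
  # hand-computed three-level case
  z <- matrix(c(0, 10, 1000), 1, 3)
  expect_equal(rescale_contrast(z, 0), matrix(c(0, 10 / 1000, 1), 1, 3))
  # constant image returned unchanged with a notice
  cst <- matrix(5, 4, 4)
  expect_message(out <- rescale_contrast(cst, 0.1), "constant")
  expect_identical(out, cst)
})

test_that("histogram thresholds separate a two-delta histogram", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  mi <- binarize_auto(img, "isodata")
  t <- attr(mi, "threshold")
  expect_gt(t, 10); expect_lt(t, 200)
  expect_identical(unname(which(mi)), which(img == 200))
  mo <- binarize_auto(img, "otsu")
  expect_identical(c(unclass(mi)), c(unclass(mo)))    # same mask on two deltas
  # isodata fixed point by hand: t = (10 + 200) / 2
  expect_equal(t, 105)
  # all-background (constant) image yields an empty mask
  expect_false(any(binarize_auto(matrix(7, 8, 8), "isodata")))
  expect_error(binarize_auto(img, "triangle"), "unknown")
})

test_that("otsu threshold agrees with an independent implementation", {
  withr::with_seed(2, {
    x <- matrix(c(rnorm(300, 30, 5), rnorm(200, 120, 15)), 25, 20)
    x <- pmax(x, 0)
    mine <- attr(binarize_auto(x, "otsu"), "threshold")
    ref <- EBImage::otsu(EBImage::Image(x / max(x)), range = c(0, 1)) * max(x)
    expect_equal(mine, ref, tolerance = 0.02 * max(x))
  })
})

test_that("dilation grows masks extensively", {
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  d <- dilate_mask(m, 1)
  expect_equal(sum(d), 9)                  # 3x3 block
  expect_true(all(d[3:5, 3:5]))
  expect_identical(dilate_mask(m, 0), m)   # 0 iterations = identity
  expect_false(any(dilate_mask(matrix(FALSE, 5, 5), 2)))
  withr::with_seed(3, {
    r <- matrix(runif(100) < 0.2, 10, 10)
    expect_true(all(dilate_mask(r, 1)[r]))  # output contains input
  })
})

test_that("watershed splits touching objects and leaves separate ones alone", {
  # disjoint disks: watershed equals connected components
  m <- disk(80, 80, 25, 25, 10) | disk(80, 80, 60, 60, 10)
  lab <- split_watershed(m, 5)
  expect_equal(max(lab), 2)
  cc <- label_components(m)
  expect_true(all((lab > 0) == (cc > 0)))
  agree <- table(lab[lab > 0], cc[cc > 0])
  expect_equal(sum(agree > 0), 2)          # one-to-one pixel partition
  # overlapping disks 1.5 radii apart are split in two
  r <- 12
  m2 <- disk(80, 80, 40, 31, r) | disk(80, 80, 40, 49, r)
  lab2 <- split_watershed(m2, 5)
  expect_equal(max(lab2), 2)
  tab <- region_properties(lab2, matrix(0, 80, 80))
  sep <- sqrt(diff(tab$centroid_row)^2 + diff(tab$centroid_col)^2)
  expect_equal(sep, 18, tolerance = 0.2)   # approx the center separation
  # empty mask
  expect_equal(max(split_watershed(matrix(FALSE, 10, 10))), 0)
})

test_that("size filter keeps areas >= threshold and matches brute force", {
  lab3 <- matrix(0L, 20, 30)
  lab3[1:7, 1:7] <- 1L                     # 49
  lab3[1:10, 10:14] <- 2L                  # 50
  lab3[11:13, 14:30] <- 3L                 # 51
  f <- filter_by_size(lab3, 50)
  areas <- tabulate(f[f > 0])
  expect_setequal(areas, c(50, 51))        # inclusive rule: area >= 50
  fs <- filter_by_size(lab3, 50, strict = TRUE)
  expect_setequal(tabulate(fs[fs > 0]), 51)
  # threshold 0 is the identity up to compaction
  expect_equal(filter_by_size(lab3, 0), compact_labels(lab3))
  # brute-force oracle on random masks
  withr::with_seed(9, {
    for (rep in 1:10) {
      m <- matrix(runif(400) < 0.35, 20, 20)
      labr <- label_components(m)
      for (thr in c(1, 3, 5, 10)) {
        got <- filter_by_size(labr, thr)
        ref <- bf_components(m)
        keep <- sum(tabulate(ref[ref > 0]) >= thr)
        expect_equal(max(got), keep)
      }
    }
  })
})

test_that("label count never increases with the size threshold", {
  withr::with_seed(21, {
    m <- matrix(runif(900) < 0.3, 30, 30)
    lab <- label_components(m)
    counts <- vapply(c(0, 2, 5, 10, 20, 50),
                     function(t) max(filter_by_size(lab, t)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("8-connected labelling matches the flood-fill oracle", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      m <- matrix(runif(225) < 0.3, 15, 15)
      mine <- label_components(m)
      ref <- bf_components(m)
      expect_equal(max(mine), max(ref))
      # identical pixel partitions up to renumbering
      agree <- table(mine[mine > 0], ref[ref > 0])
      expect_equal(sum(agree > 0), max(ref))
    }
  })
})

test_that("multistep segmentation is deterministic and leaves the input alone", {
  sim <- simulate_spheroid_slice(scene_spec(n_cells = 80,
                                            image_size = c(256L, 256L),
                                            spheroid_radius = 100, seed = 14))
  x <- get_channel(sim$image, "DAPI")
  xc <- x + 0
  l1 <- multistep_segment(x)
  l2 <- multistep_segment(x)
  expect_identical(l1, l2)
  expect_identical(x, xc)
  expect_gt(max(l1), 0)
  # no label below the size threshold survives
  expect_true(all(tabulate(l1[l1 > 0]) >= 50))
})

test_that("well-separated scenes give one label per cell in both routes", {
  sp <- scene_spec(culture_mode = "monolayer", n_cells = 40,
                   image_size = c(320L, 320L), cell_radius_mean = 9,
                   min_dist_factor = 1.6, noise_gaussian_sd = 0,
                   noise_poisson = FALSE, seed = 2)
  sim <- simulate_monolayer(sp)
  x <- get_channel(sim$image, "DAPI")
  expect_equal(max(multistep_segment(x)), 40)
  expect_equal(max(simple_threshold_segment(x)), 40)
})

test_that("noise-only fields segment to nothing", {
  sp <- scene_spec(culture_mode = "monolayer", n_cells = 0,
                   image_size = c(256L, 256L), seed = 5)
  sim <- simulate_monolayer(sp)
  expect_equal(max(multistep_segment(get_channel(sim$image, "DAPI"))), 0)
  # all-zero image too
  expect_equal(max(simple_threshold_segment(matrix(0, 64, 64))), 0)
})
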