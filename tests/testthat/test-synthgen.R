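test_that("identical spec and seed give bit-identical scenes", {
  sp <- scene_spec(n_cells = 60, image_size = c(192L, 192L),
                   spheroid_radius = 70, seed = 7)
  a <- simulate_spheroid_slice(sp)
  b <- simulate_spheroid_slice(sp)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("ground-truth zones agree with the true masks", {
  sp <- scene_spec(n_cells = 120, seed = 3)
  sim <- simulate_spheroid_slice(sp)
  cells <- sim$truth$cells
  idx <- cbind(pmin(pmax(round(cells$row), 1), nrow(sim$truth$outside_mask)),
               pmin(pmax(round(cells$col), 1), ncol(sim$truth$outside_mask)))
  expect_true(all(sim$truth$outside_mask[idx[cells$zone == "outside", , drop = FALSE]]))
  expect_true(all(sim$truth$inside_mask[idx[cells$zone == "inside", , drop = FALSE]]))
  # rim cells carry the enrichment factor in their true level
  expect_equal(unique(cells$marker_level[cells$zone == "outside"]),
               sp$marker_base_level * sp$rim_enrichment_factor)
  expect_equal(unique(cells$marker_level[cells$zone == "inside"]),
               sp$marker_base_level)
})

test_that("with noise off, measured per-cell marker means equal true levels", {
  sp <- scene_spec(n_cells = 80, image_size = c(256L, 256L),
                   spheroid_radius = 100, noise_gaussian_sd = 0,
                   noise_poisson = FALSE, background_level = 0, seed = 11)
  sim <- simulate_spheroid_slice(sp)
  tab <- region_properties(sim$truth$labels, sim$image)
  lev <- sim$truth$cells$marker_level[tab$label]
  expect_true(all(abs(tab$mean_marker - lev) <= 0.01 * lev))
  # single-cell closed-form check: channel sum over the cell footprint
  sp1 <- scene_spec(culture_mode = "monolayer", n_cells = 1,
                    image_size = c(64L, 64L), noise_gaussian_sd = 0,
                    noise_poisson = FALSE, background_level = 0, seed = 4)
  sim1 <- simulate_monolayer(sp1)
  area <- sum(sim1$truth$labels > 0)
  expect_equal(sum(get_channel(sim1$image, "marker")),
               sim1$truth$cells$marker_level[1] * area, tolerance = 1e-9)
})

test_that("rim factor 1 makes rim and core cells statistically identical", {
  sp <- scene_spec(n_cells = 100, rim_enrichment_factor = 1,
                   noise_gaussian_sd = 0, noise_poisson = FALSE, seed = 8)
  sim <- simulate_spheroid_slice(sp)
  cells <- sim$truth$cells
  expect_equal(mean(cells$marker_level[cells$zone == "outside"]),
               mean(cells$marker_level[cells$zone == "inside"]))
})

test_that("positivity bookkeeping records the exact binomial draw", {
  sp <- scene_spec(culture_mode = "monolayer", n_cells = 400,
                   image_size = c(384L, 384L), positive_fraction = 0.3,
                   seed = 13)
  sim <- simulate_monolayer(sp)
  cells <- sim$truth$cells
  expect_equal(sum(cells$positive), sum(cells$marker_level > sp$marker_base_level))
  expect_equal(unique(cells$marker_level[cells$positive]),
               sp$marker_base_level * sp$positive_boost)
})

test_that("empty scenes and hollow cores behave as declared", {
  sp0 <- scene_spec(culture_mode = "monolayer", n_cells = 0,
                    image_size = c(64L, 64L), seed = 1)
  sim0 <- simulate_monolayer(sp0)
  expect_true(all(sim0$truth$labels == 0L))
  expect_equal(nrow(sim0$truth$cells), 0)

  sph <- scene_spec(n_cells = 80, hollow_core_fraction = 0.3,
                    image_size = c(256L, 256L), spheroid_radius = 100, seed = 6)
  simh <- simulate_spheroid_slice(sph)
  core_r <- 0.3 * 100
  d <- sqrt((simh$truth$cells$row - 128.5)^2 + (simh$truth$cells$col - 128.5)^2)
  expect_true(all(d >= core_r))
  # no rendered cell pixel falls inside the hollow core
  h <- nrow(simh$truth$labels)
  core <- outer((seq_len(h) - 128.5)^2, (seq_len(h) - 128.5)^2, "+") <= core_r^2
  expect_true(all(simh$truth$labels[core] == 0L))
})

test_that("tear artifact removes cells along the cut but keeps true-border zones", {
  sp <- scene_spec(n_cells = 100, tear = TRUE, tear_width = 24, seed = 9)
  sim <- simulate_spheroid_slice(sp)
  cells <- sim$truth$cells
  n <- c(cos(sp$tear_angle), sin(sp$tear_angle))
  off <- (cells$row - 192.5) * n[1] + (cells$col - 192.5) * n[2]
  expect_true(all(abs(off) >= sp$tear_width / 2))
  # zone assignment still keyed to the outer boundary only
  d <- sqrt((cells$row - 192.5)^2 + (cells$col - 192.5)^2)
  expect_equal(cells$zone == "outside", d > sp$spheroid_radius - sp$rim_width)
})

test_that("infeasible packing fails loudly with the achieved count", {
  sp <- scene_spec(culture_mode = "monolayer", n_cells = 5000,
                   image_size = c(64L, 64L), seed = 1)
  expect_error(simulate_monolayer(sp), "infeasible cell packing")
})

test_that("growth series truths follow the halo schedule", {
  gs <- growth_series_spec(days = c(7, 14, 21), compact_radius = c(40, 50, 60),
                           halo_cell_count = c(0, 60, 200), seed = 4)
  sim <- simulate_growth_series(gs)
  expect_equal(sim$true_compact_fraction[1], 1)        # no halo
  expect_true(all(diff(sim$true_compact_fraction) <= 0)) # monotone halo
  # compact area equals the rendered disk pixel count
  expect_equal(sim$true_compact_px,
               vapply(c(40, 50, 60), function(r) sum(disk(384, 384, 192.5, 192.5, r)),
                      numeric(1)))
})

test_that("gel rendering matches its declared truth", {
  lanes <- gel_lanes_standard()
  g <- simulate_gel(gel_spec(lanes, noise_sd = 0))
  expect_equal(g$truth$integral[!g$truth$control], c(1000, 2000, 4000))
  # the same spec and seed render identical gel images
  sp2 <- gel_spec(lanes, noise_sd = 0.5, seed = 3)
  expect_identical(simulate_gel(sp2)$image, simulate_gel(sp2)$image)
  # noise propagation: rendered integral near analytic value
  gn <- simulate_gel(gel_spec(lanes[1], noise_sd = 0.5, seed = 2))
  ann <- gn$annotations[1, ]
  win <- ann$row_lo:ann$row_hi
  rendered <- sum(gn$image[win, ann$col_lo:ann$col_hi]) -
    2 * length(win) * 24   # subtract known background
  npix <- length(win) * 24
  expect_lt(abs(rendered - 1000), 3 * 0.5 * sqrt(npix) + 1)
  # overlapping bands are flagged
  close_lane <- list(data.frame(band = c("a", "ctrl"), position = c(100, 104),
                                integral = c(500, 500), control = c(FALSE, TRUE)))
  expect_length(simulate_gel(gel_spec(close_lane, noise_sd = 0))$warnings, 1)
})
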