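#' Specification of a synthetic microscopy scene
#'
#' Parameterizes a simulated cryosection slice of a spheroid (densely
#' packed nuclei inside a roughly circular section, optional cell-free
#' core, a marker channel with configurable rim enrichment) or a sparse 2D
#' monolayer field. Together with the seed, a spec fully determines every
#' output byte, so simulated scenes double as exact ground truth for the
#' segmentation and quantification modules.
#'
#' Default levels model a typical confocal export in arbitrary 8-bit-like
#' units: nuclei peaking near 150 AU over a ~10 AU background, shot
#' (Poisson) noise on the signal plus 5 AU Gaussian read noise. The default
#' rim enrichment factor 1.33 corresponds to rim cells about 33% brighter
#' than core cells; marker fold experiments between 3D and 2D cultures are
#' expressed by scaling `marker_base_level` between two scenes.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param culture_mode `"spheroid"` or `"monolayer"`.
#' @param spheroid_radius section radius in pixels (spheroid mode).
#' @param hollow_core_fraction fraction of the radius that is cell-free at
#'   the center (0 = solid; 0.3 models older spheroids with empty cores).
#' @param n_cells number of cells to place.
#' @param cell_radius_mean,cell_radius_sd nucleus radius distribution (px).
#' @param dapi_level peak nuclear intensity in the DAPI channel (AU).
#' @param marker_base_level peak marker intensity of a baseline cell (AU).
#' @param rim_enrichment_factor multiplicative marker boost for cells whose
#'   center lies in the rim zone (1 = no enrichment).
#' @param rim_width width of the rim zone, from the section boundary
#'   inwards (px).
#' @param positive_fraction fraction of cells positive for a binary marker.
#' @param positive_boost marker multiplier for positive cells.
#' @param noise_gaussian_sd additive Gaussian noise sd (AU).
#' @param noise_poisson apply Poisson (shot) noise to the noiseless signal.
#' @param background_level constant background offset (AU).
#' @param min_dist_factor placement rule: two centers must be at least
#'   `min_dist_factor * (r_i + r_j)` apart. The default 0.8 allows mild
#'   overlap (exercising watershed splitting); values above ~1.2 give
#'   well-separated cells.
#' @param tear simulate a straight tear artifact: a cell-free cut through
#'   the section. Cells along the cut receive no rim boost (only true
#'   border proximity counts), so rim staining appears only on the real
#'   boundary.
#' @param tear_width width of the tear strip (px).
#' @param tear_angle orientation of the tear (radians).
#' @param seed integer RNG seed.
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(384L, 384L),
                       culture_mode = c("spheroid", "monolayer"),
                       spheroid_radius = 150,
                       hollow_core_fraction = 0,
                       n_cells = 200L,
                       cell_radius_mean = 6,
                       cell_radius_sd = 0.8,
                       dapi_level = 150,
                       marker_base_level = 60,
                       rim_enrichment_factor = 1.33,
                       rim_width = 24,
                       positive_fraction = 0,
                       positive_boost = 3,
                       noise_gaussian_sd = 5,
                       noise_poisson = TRUE,
                       background_level = 10,
                       min_dist_factor = 0.8,
                       tear = FALSE,
                       tear_width = 20,
                       tear_angle = pi / 5,
                       seed = 1L) {
  culture_mode <- match.arg(culture_mode)
  stopifnot(length(image_size) == 2, all(image_size >= 32), min_dist_factor > 0,
            n_cells >= 0, cell_radius_mean > 0, cell_radius_sd >= 0,
            rim_enrichment_factor >= 0,
            positive_fraction >= 0, positive_fraction <= 1,
            positive_boost > 0, noise_gaussian_sd >= 0,
            background_level >= 0, hollow_core_fraction >= 0,
            hollow_core_fraction < 1, rim_width > 0)
  if (culture_mode == "spheroid") {
    if (2 * spheroid_radius + 4 > min(image_size))
      stop("spheroid does not fit in the image", call. = FALSE)
  }
  structure(as.list(environment()), class = "scene_spec")
}

# radially symmetric smooth nucleus profile (cosine falloff, mimics blur)
.cell_profile <- function(d, r) ifelse(d <= r, 0.5 * (1 + cos(pi * d / r)), 0)

# rejection-sampling placement of cell centers; mild overlap allowed by
# default (minimum center distance 0.8 * (r_i + r_j)); bounded attempts
.place_cells <- function(n, radii, sample_center, accept,
                         min_dist_factor = 0.8, max_attempts = 10000L) {
  rows <- numeric(0); cols <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      p <- sample_center(radii[i])
      if (!accept(p[1], p[2], radii[i])) next
      if (length(rows)) {
        d2 <- (rows - p[1])^2 + (cols - p[2])^2
        if (any(d2 < (min_dist_factor * (radii[seq_along(rows)] + radii[i]))^2)) next
      }
      rows <- c(rows, p[1]); cols <- c(cols, p[2]); placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible cell packing: placed ", length(rows), " of ", n,
           " cells before exhausting ", max_attempts, " attempts", call. = FALSE)
  }
  list(row = rows, col = cols)
}

# render cells into DAPI/marker planes and a true label map.
# pixels covered by several cells belong to the relatively closest center
# (smallest d/r). DAPI is additive with a smooth falloff, so neighbouring
# nuclei blur into each other as under a confocal PSF; the marker is a
# cell-intrinsic stain confined to each cell's claimed territory, so every
# marker photon is attributable to exactly one cell and per-cell truth is
# well defined.
.render_cells <- function(h, w, cells, dapi_level) {
  dapi <- matrix(0, h, w)
  labels <- matrix(0L, h, w)
  claim <- matrix(Inf, h, w)       # d/r of current owner
  n <- nrow(cells)
  for (i in seq_len(n)) {
    r <- cells$radius[i]
    ri <- max(1L, floor(cells$row[i] - r)):min(h, ceiling(cells$row[i] + r))
    ci <- max(1L, floor(cells$col[i] - r)):min(w, ceiling(cells$col[i] + r))
    d <- sqrt(outer((ri - cells$row[i])^2, (ci - cells$col[i])^2, "+"))
    prof <- .cell_profile(d, r)
    dapi[ri, ci] <- dapi[ri, ci] + dapi_level * prof
    rel <- d / r
    inside <- d <= r
    win <- inside & rel < claim[ri, ci]
    sub <- claim[ri, ci]; sub[win] <- rel[win]; claim[ri, ci] <- sub
    lsub <- labels[ri, ci]; lsub[win] <- i; labels[ri, ci] <- lsub
  }
  marker <- matrix(0, h, w)
  own <- labels > 0L
  if (any(own)) {
    prof <- 0.5 * (1 + cos(pi * pmin(claim[own], 1)))
    lab <- labels[own]
    # normalize each cell's profile to unit mean over its territory, so the
    # per-cell mean marker intensity equals the true level exactly
    pm <- numeric(n); cnt <- tabulate(lab, nbins = n)
    agg <- rowsum(prof, lab)
    pm[as.integer(rownames(agg))] <- agg[, 1]
    pm <- pm / pmax(cnt, 1)
    marker[own] <- cells$marker_level[lab] * prof / pm[lab]
  }
  list(dapi = dapi, marker = marker, labels = labels)
}

.apply_noise <- function(plane, spec) {
  x <- plane + spec$background_level
  if (isTRUE(spec$noise_poisson)) x <- matrix(stats::rpois(length(x), x), nrow(x))
  if (spec$noise_gaussian_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, spec$noise_gaussian_sd), nrow(x))
  pmax(x, 0)
}

.disk_mask <- function(h, w, crow, ccol, radius) {
  d2 <- outer((seq_len(h) - crow)^2, (seq_len(w) - ccol)^2, "+")
  d2 <= radius^2
}

#' Simulate a spheroid cryosection slice with exact ground truth
#'
#' Renders a DAPI channel (nuclei as radially smooth disks), a marker
#' channel whose per-cell level is
#' `marker_base_level * rim_enrichment_factor^(cell in rim) *
#' positive_boost^(cell positive)`, and records exact per-cell truth:
#' label map, centers, radii, zone, true marker level, positivity, plus
#' the true section / rim / core masks.
#'
#' @param spec a [scene_spec()] with `culture_mode = "spheroid"`.
#' @return list with `image` (a [multichannel_image()] with channels
#'   `DAPI`, `marker`) and `truth` (list: `labels`, `cells` tibble,
#'   `spheroid_mask`, `inside_mask`, `outside_mask`).
#' @export
simulate_spheroid_slice <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"), spec$culture_mode == "spheroid")
  h <- spec$image_size[1]; w <- spec$image_size[2]
  crow <- (h + 1) / 2; ccol <- (w + 1) / 2
  R <- spec$spheroid_radius
  core <- spec$hollow_core_fraction * R
  withr::with_seed(spec$seed, {
    radii <- pmax(stats::rnorm(spec$n_cells, spec$cell_radius_mean,
                               spec$cell_radius_sd), 2)
    tear_n <- c(cos(spec$tear_angle), sin(spec$tear_angle))
    # centers may reach within 2 px of the section border: edge nuclei are
    # clipped by the section boundary, as in real cryosections
    accept <- function(r, c, rad) {
      d <- sqrt((r - crow)^2 + (c - ccol)^2)
      if (d > R - 2 || d < core + rad * (core > 0)) return(FALSE)
      if (isTRUE(spec$tear)) {
        off <- (r - crow) * tear_n[1] + (c - ccol) * tear_n[2]
        if (abs(off) < spec$tear_width / 2) return(FALSE)
      }
      TRUE
    }
    sample_center <- function(rad) {
      ang <- stats::runif(1, 0, 2 * pi)
      rr <- sqrt(stats::runif(1, (core)^2, (R - 2)^2))
      c(crow + rr * sin(ang), ccol + rr * cos(ang))
    }
    pos <- .place_cells(spec$n_cells, radii, sample_center, accept, spec$min_dist_factor)
    dist_center <- sqrt((pos$row - crow)^2 + (pos$col - ccol)^2)
    zone <- ifelse(dist_center > R - spec$rim_width, "outside", "inside")
    positive <- stats::runif(spec$n_cells) < spec$positive_fraction
    level <- spec$marker_base_level *
      ifelse(zone == "outside", spec$rim_enrichment_factor, 1) *
      ifelse(positive, spec$positive_boost, 1)
    cells <- tibble::tibble(cell = seq_len(spec$n_cells),
                            row = pos$row, col = pos$col, radius = radii,
                            zone = zone, positive = positive,
                            marker_level = level)
    rend <- .render_cells(h, w, cells, spec$dapi_level)
    # expected signal-only marker mean over each cell's true pixel set
    cells$marker_mean <- .true_marker_means(rend, cells)
    img <- multichannel_image(list(
      DAPI = .apply_noise(rend$dapi, spec),
      marker = .apply_noise(rend$marker, spec)))
    spheroid_mask <- .disk_mask(h, w, crow, ccol, R)
    outside_mask <- spheroid_mask & !.disk_mask(h, w, crow, ccol, R - spec$rim_width)
    list(image = img,
         truth = list(labels = rend$labels, cells = cells,
                      spheroid_mask = spheroid_mask,
                      inside_mask = spheroid_mask & !outside_mask,
                      outside_mask = outside_mask))
  })
}

.true_marker_means <- function(rend, cells) {
  if (nrow(cells) == 0L) return(numeric(0))
  v <- as.numeric(rend$marker)[rend$labels > 0L]
  l <- rend$labels[rend$labels > 0L]
  area <- tabulate(l, nbins = nrow(cells))
  sums <- numeric(nrow(cells))
  agg <- rowsum(v, l)
  sums[as.integer(rownames(agg))] <- agg[, 1]
  ifelse(area > 0, sums / pmax(area, 1), NA_real_)
}

#' Simulate a sparse 2D monolayer field
#'
#' Cells are placed over the whole frame with the same mild-overlap rule as
#' in spheroid mode but no section mask; every cell's marker level is the
#' base level (times the positive boost where applicable). A 3D-vs-2D fold
#' experiment is expressed by giving the spheroid scene a base level equal
#' to `fold x` the monolayer base level.
#'
#' @param spec a [scene_spec()] with `culture_mode = "monolayer"`.
#' @return as [simulate_spheroid_slice()]; the truth masks are absent.
#' @export
simulate_monolayer <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"), spec$culture_mode == "monolayer")
  h <- spec$image_size[1]; w <- spec$image_size[2]
  withr::with_seed(spec$seed, {
    radii <- pmax(stats::rnorm(spec$n_cells, spec$cell_radius_mean,
                               spec$cell_radius_sd), 2)
    accept <- function(r, c, rad)
      r > rad + 1 && r < h - rad && c > rad + 1 && c < w - rad
    sample_center <- function(rad)
      c(stats::runif(1, 1, h), stats::runif(1, 1, w))
    pos <- .place_cells(spec$n_cells, radii, sample_center, accept, spec$min_dist_factor)
    positive <- stats::runif(spec$n_cells) < spec$positive_fraction
    level <- spec$marker_base_level * ifelse(positive, spec$positive_boost, 1)
    cells <- tibble::tibble(cell = seq_len(spec$n_cells),
                            row = pos$row, col = pos$col, radius = radii,
                            zone = "ungated", positive = positive,
                            marker_level = level)
    rend <- .render_cells(h, w, cells, spec$dapi_level)
    cells$marker_mean <- .true_marker_means(rend, cells)
    img <- multichannel_image(list(
      DAPI = .apply_noise(rend$dapi, spec),
      marker = .apply_noise(rend$marker, spec)))
    list(image = img, truth = list(labels = rend$labels, cells = cells))
  })
}

#' Specification of a phase-contrast growth series
#'
#' One dark compact spheroid body per day on a bright background, plus a
#' configurable halo of scattered dark cells outside the compact body,
#' emulating 3D cultures that shed outward-moving cells as they age.
#'
#' @param days days in vitro (DiV) of the series.
#' @param compact_radius radius (px) of the compact body per day (recycled).
#' @param halo_cell_count number of scattered halo cells per day (recycled).
#' @param image_size `c(height, width)`.
#' @param halo_cell_radius radius of a halo cell speck (px).
#' @param background_level,foreground_level bright background / dark culture
#'   grey levels (AU).
#' @param noise_gaussian_sd additive noise (AU).
#' @param seed integer RNG seed.
#' @return list of class `growth_series_spec`.
#' @export
growth_series_spec <- function(days = c(7, 14, 21, 25),
                               compact_radius = c(40, 55, 65, 70),
                               halo_cell_count = c(0, 40, 150, 250),
                               image_size = c(384L, 384L),
                               halo_cell_radius = 3,
                               background_level = 200,
                               foreground_level = 60,
                               noise_gaussian_sd = 5,
                               seed = 1L) {
  compact_radius <- rep_len(compact_radius, length(days))
  halo_cell_count <- rep_len(halo_cell_count, length(days))
  stopifnot(all(compact_radius > 0), all(halo_cell_count >= 0),
            foreground_level < background_level)
  structure(as.list(environment()), class = "growth_series_spec")
}

#' Simulate a phase-contrast growth series with true areas
#'
#' @param spec a [growth_series_spec()].
#' @return tibble with one row per day: `div`, `image` (list column of
#'   matrices), `true_compact_px`, `true_total_px`, `true_compact_fraction`.
#'   True areas are pixel counts of the rendered masks, not analytic disks.
#' @export
simulate_growth_series <- function(spec) {
  stopifnot(inherits(spec, "growth_series_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  crow <- (h + 1) / 2; ccol <- (w + 1) / 2
  withr::with_seed(spec$seed, {
    out <- purrr::map(seq_along(spec$days), function(i) {
      R <- spec$compact_radius[i]
      compact <- .disk_mask(h, w, crow, ccol, R)
      halo <- matrix(FALSE, h, w)
      n_halo <- spec$halo_cell_count[i]
      if (n_halo > 0) {
        rmax <- min(h, w) / 2 - spec$halo_cell_radius - 2
        k <- 0L; attempts <- 0L
        while (k < n_halo && attempts < 200L * n_halo) {
          attempts <- attempts + 1L
          ang <- stats::runif(1, 0, 2 * pi)
          rr <- sqrt(stats::runif(1, (R + spec$halo_cell_radius + 2)^2, rmax^2))
          m <- .disk_mask(h, w, crow + rr * sin(ang), ccol + rr * cos(ang),
                          spec$halo_cell_radius)
          if (any(m & compact)) next
          halo <- halo | m
          k <- k + 1L
        }
      }
      img <- matrix(spec$background_level, h, w)
      img[compact | halo] <- spec$foreground_level
      if (spec$noise_gaussian_sd > 0)
        img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_gaussian_sd), h)
      img <- pmax(img, 0)
      tibble::tibble(div = spec$days[i], image = list(img),
                     true_compact_px = sum(compact),
                     true_total_px = sum(compact) + sum(halo & !compact))
    })
    out <- dplyr::bind_rows(out)
    out$true_compact_fraction <- out$true_compact_px / out$true_total_px
    out
  })
}

#' Specification of a synthetic gel-blot image
#'
#' Each lane is a vertical strip with Gaussian band profiles along the lane
#' (row) axis; band integrals are exact by construction. Every lane must
#' include a loading-control band.
#'
#' @param lanes list of data frames, one per lane, with columns `band`
#'   (name), `position` (row of band center), `integral` (total signal),
#'   `control` (logical; exactly one `TRUE` per lane).
#' @param image_height rows of the gel image.
#' @param lane_width,lane_gap lane geometry (px).
#' @param band_sigma Gaussian band sd along the lane axis (px).
#' @param background constant background (AU per pixel).
#' @param noise_sd additive Gaussian noise (AU per pixel); the default 0.5
#'   over a background of 2 gives a band-peak signal-to-noise ratio of
#'   about 8 for an integral of 1000, typical of a decent blot scan.
#' @param seed integer RNG seed.
#' @return list of class `gel_spec`.
#' @export
gel_spec <- function(lanes,
                     image_height = 256L,
                     lane_width = 24L,
                     lane_gap = 12L,
                     band_sigma = 4,
                     background = 2,
                     noise_sd = 0.5,
                     seed = 1L) {
  stopifnot(is.list(lanes), length(lanes) >= 1)
  for (ln in lanes) {
    stopifnot(all(c("band", "position", "integral", "control") %in% names(ln)),
              all(ln$integral > 0), sum(ln$control) == 1)
  }
  structure(list(lanes = lanes, image_height = as.integer(image_height),
                 lane_width = as.integer(lane_width),
                 lane_gap = as.integer(lane_gap), band_sigma = band_sigma,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "gel_spec")
}

#' Render a synthetic gel image with per-band truth and annotations
#'
#' @param spec a [gel_spec()].
#' @return list with `image` (matrix), `truth` (tibble of true integrals),
#'   `annotations` (tibble of lane column spans and band row windows at
#'   +/- 4 sigma, ready for [densitometry_ratio()]), and `warnings`
#'   (character; notes bands closer than 2 sigma).
#' @export
simulate_gel <- function(spec) {
  stopifnot(inherits(spec, "gel_spec"))
  nl <- length(spec$lanes)
  h <- spec$image_height
  w <- nl * spec$lane_width + (nl + 1) * spec$lane_gap
  img <- matrix(spec$background, h, w)
  truth <- list(); ann <- list(); warns <- character(0)
  for (l in seq_len(nl)) {
    ln <- spec$lanes[[l]]
    col_lo <- spec$lane_gap * l + spec$lane_width * (l - 1) + 1
    col_hi <- col_lo + spec$lane_width - 1
    pos <- sort(ln$position)
    if (length(pos) > 1 && any(diff(pos) < 2 * spec$band_sigma))
      warns <- c(warns, paste0("lane ", l, ": bands closer than 2 sigma overlap"))
    prof <- numeric(h)
    for (b in seq_len(nrow(ln)))
      prof <- prof + ln$integral[b] *
        stats::dnorm(seq_len(h), ln$position[b], spec$band_sigma)
    img[, col_lo:col_hi] <- img[, col_lo:col_hi] + prof / spec$lane_width
    truth[[l]] <- tibble::tibble(lane = l, band = ln$band,
                                 position = ln$position,
                                 integral = ln$integral, control = ln$control)
    ann[[l]] <- tibble::tibble(lane = l, col_lo = col_lo, col_hi = col_hi,
                               band = ln$band,
                               row_lo = pmax(1L, floor(ln$position - 4 * spec$band_sigma)),
                               row_hi = pmin(h, ceiling(ln$position + 4 * spec$band_sigma)),
                               control = ln$control)
  }
  if (spec$noise_sd > 0) {
    img <- withr::with_seed(spec$seed,
      img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h))
    img <- pmax(img, 0)
  }
  list(image = img, truth = dplyr::bind_rows(truth),
       annotations = dplyr::bind_rows(ann), warnings = warns)
}
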