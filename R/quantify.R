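#' Estimate the background intensity level
#'
#' Median raw intensity outside a mask (or over the whole frame when no
#' mask is given). Ratios of means are offset-sensitive, so rim-enrichment
#' and fold-change computations should subtract this estimate.
#'
#' @param image numeric matrix (one raw channel) or [multichannel_image()].
#' @param mask logical mask of the foreground to exclude (e.g. the section
#'   mask); `NULL` uses all pixels.
#' @param channel channel name when `image` is multi-channel.
#' @return scalar background level (AU).
#' @export
estimate_background <- function(image, mask = NULL, channel = "marker") {
  x <- if (inherits(image, "mcimage")) get_channel(image, channel) else image
  stopifnot(is.matrix(x))
  if (is.null(mask)) return(stats::median(x))
  stopifnot(identical(dim(x), dim(mask)))
  if (!any(!mask)) return(stats::median(x))
  stats::median(x[!mask])
}

#' Rim/core enrichment bookkeeping
#'
#' Implements the difference-and-divide scheme over per-ROI summed
#' intensities: the total and outside sums are accumulated directly, the
#' inside sum is obtained as `sum_total - sum_outside`, each sum is divided
#' by its ROI count to give the zone means, and the enrichment is
#' `mean_outside / mean_inside` (reported also as
#' `percent_brighter = 100 * (ratio - 1)`). These identities hold exactly
#' by construction and are part of the returned object.
#'
#' A per-pixel `background` level (see [estimate_background()]) is
#' subtracted from every ROI as `background * area_px` before summing,
#' because the ratio is offset-sensitive; the default 0 leaves raw sums.
#'
#' @param table a gated, zone-assigned [region_properties()] table; rows
#'   with `zone == "ungated"` are ignored.
#' @param channel channel name (uses the `sum_<channel>` column).
#' @param background per-pixel background level (AU).
#' @return object of class `rim_enrichment`: list with the zone sums,
#'   counts, means, `outside_inside_ratio`, and `percent_brighter`.
#' @export
rim_enrichment <- function(table, channel = "marker", background = 0) {
  scol <- paste0("sum_", channel)
  if (!scol %in% names(table))
    stop("no column '", scol, "' in the region table", call. = FALSE)
  if (!"zone" %in% names(table))
    stop("table has no zone assignment; run assign_zones() first", call. = FALSE)
  tab <- table[table$zone %in% c("inside", "outside"), , drop = FALSE]
  n_outside <- sum(tab$zone == "outside")
  n_inside <- sum(tab$zone == "inside")
  if (n_outside < 1) stop("no ROIs in the outside (rim) zone", call. = FALSE)
  if (n_inside < 1) stop("no ROIs in the inside (core) zone", call. = FALSE)
  adj <- tab[[scol]] - background * tab$area_px
  sum_total <- sum(adj)
  sum_outside <- sum(adj[tab$zone == "outside"])
  sum_inside <- sum_total - sum_outside
  n_total <- n_outside + n_inside
  mean_total <- sum_total / n_total
  mean_outside <- sum_outside / n_outside
  mean_inside <- sum_inside / n_inside
  ratio <- mean_outside / mean_inside
  structure(list(channel = channel, background = background,
                 sum_total = sum_total, n_total = n_total,
                 sum_outside = sum_outside, n_outside = n_outside,
                 sum_inside = sum_inside, n_inside = n_inside,
                 mean_total = mean_total, mean_outside = mean_outside,
                 mean_inside = mean_inside,
                 outside_inside_ratio = ratio,
                 percent_brighter = 100 * (ratio - 1)),
            class = "rim_enrichment")
}

#' @export
print.rim_enrichment <- function(x, ...) {
  cat("<rim_enrichment> channel ", x$channel, "\n", sep = "")
  cat(sprintf("  outside: n = %d, mean ROI sum = %.4g\n", x$n_outside, x$mean_outside))
  cat(sprintf("  inside:  n = %d, mean ROI sum = %.4g\n", x$n_inside, x$mean_inside))
  cat(sprintf("  outside/inside ratio = %.4f (%.1f%% brighter at the rim)\n",
              x$outside_inside_ratio, x$percent_brighter))
  invisible(x)
}

#' Tidy a rim-enrichment result into a one-row tibble
#' @param x a `rim_enrichment` object.
#' @param ... unused.
#' @method tidy rim_enrichment
#' @export
tidy.rim_enrichment <- function(x, ...) {
  tibble::tibble(channel = x$channel,
                 n_total = x$n_total, n_outside = x$n_outside,
                 n_inside = x$n_inside,
                 sum_total = x$sum_total, sum_outside = x$sum_outside,
                 sum_inside = x$sum_inside,
                 mean_total = x$mean_total, mean_outside = x$mean_outside,
                 mean_inside = x$mean_inside,
                 outside_inside_ratio = x$outside_inside_ratio,
                 percent_brighter = x$percent_brighter)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Condition-level fluorescence summary
#'
#' Summarizes per-ROI mean intensities across images of each condition.
#' Both granularities are reported: ROI-level statistics (every ROI one
#' observation) and image-level statistics (each image contributes its
#' mean of ROI means), because pooling ROIs across images pseudoreplicates;
#' downstream statistics should normally use the image-level values.
#'
#' @param tables named list: condition name -> one region table or a list
#'   of region tables (one per image).
#' @param channel channel name (uses the `mean_<channel>` column).
#' @param background per-pixel background level subtracted from ROI means;
#'   a scalar, or a named list parallel to `tables`.
#' @return tibble with one row per condition: `condition`, `n_images`,
#'   `n_rois`, `mean_roi`, `sd_roi`, `mean_image`, `sd_image` (sample SD;
#'   0 where n = 1).
#' @export
condition_summary <- function(tables, channel = "marker", background = 0) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  mcol <- paste0("mean_", channel)
  rows <- purrr::imap(tables, function(tabs, cond) {
    if (is.data.frame(tabs)) tabs <- list(tabs)
    bg <- if (is.list(background)) background[[cond]] else background
    bg <- rep_len(bg, length(tabs))
    vals <- purrr::map2(tabs, bg, function(tb, b) {
      if (!mcol %in% names(tb))
        stop("no column '", mcol, "' in a table of condition '", cond, "'",
             call. = FALSE)
      tb[[mcol]] - b
    })
    roi <- unlist(vals)
    img_means <- vapply(vals, mean, numeric(1))
    tibble::tibble(condition = cond,
                   n_images = length(tabs), n_rois = length(roi),
                   mean_roi = mean(roi),
                   sd_roi = if (length(roi) > 1) stats::sd(roi) else 0,
                   mean_image = mean(img_means),
                   sd_image = if (length(img_means) > 1) stats::sd(img_means) else 0)
  })
  dplyr::bind_rows(rows)
}

#' Marker-positive cell fraction
#'
#' Classifies ROIs as marker-positive by thresholding their per-ROI mean
#' intensities. Rules:
#' * `"otsu"` (default) — Otsu threshold on the per-ROI means of this image;
#' * `"fixed"` — a user-supplied threshold (`threshold=`);
#' * `"gmm2"` — two-component Gaussian mixture; positives are the ROIs
#'   classified into the higher-mean component.
#'
#' Positives satisfy `mean intensity > threshold` (for `gmm2` the
#' equivalent posterior rule). The applied rule and threshold are part of
#' the result.
#'
#' @param table a region table.
#' @param channel channel name.
#' @param rule `"otsu"`, `"fixed"` or `"gmm2"`.
#' @param threshold threshold value for `rule = "fixed"`.
#' @return one-row tibble of class `positive_fraction`: `marker`,
#'   `n_cells`, `n_positive`, `fraction`, `threshold`, `rule`.
#' @export
positive_fraction <- function(table, channel = "marker",
                              rule = c("otsu", "fixed", "gmm2"),
                              threshold = NULL) {
  rule <- match.arg(rule)
  mcol <- paste0("mean_", channel)
  if (!mcol %in% names(table))
    stop("no column '", mcol, "' in the region table", call. = FALSE)
  v <- table[[mcol]]
  n <- length(v)
  if (rule %in% c("otsu", "gmm2") && n < 2)
    stop("rule '", rule, "' needs at least 2 ROIs; got ", n, call. = FALSE)
  if (rule == "fixed" && is.null(threshold))
    stop("rule 'fixed' requires `threshold`", call. = FALSE)
  if (rule == "otsu") threshold <- .threshold_otsu(matrix(v, 1))
  if (rule == "gmm2") {
    fit <- Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
    hi <- which.max(fit$parameters$mean)
    pos <- fit$classification == hi
    threshold <- max(v[!pos][v[!pos] < min(v[pos])], -Inf)
    n_pos <- sum(pos)
  }
  if (rule != "gmm2") n_pos <- sum(v > threshold)
  out <- tibble::tibble(marker = channel, n_cells = n,
                        n_positive = as.integer(n_pos),
                        fraction = if (n > 0) n_pos / n else NA_real_,
                        threshold = as.numeric(threshold), rule = rule)
  class(out) <- c("positive_fraction", class(out))
  out
}

#' Loading-control-normalized band densitometry
#'
#' For each lane, the intensity profile along the lane (row) axis is
#' integrated over the lane's column span; a baseline is subtracted and
#' each band integral is the sum of the corrected profile over its
#' annotated row window. The default baseline is the median profile value
#' over the rows outside every annotated band window (unbiased for the
#' flat background of a film scan); a morphological-opening baseline
#' (rolling minimum then maximum of a lightly smoothed profile) is
#' available for sloping backgrounds. Relative intensities are
#' band / loading-control per lane.
#'
#' @param gel numeric gel image matrix (bands bright on dark background).
#' @param annotations tibble with one row per band: `lane`, `col_lo`,
#'   `col_hi`, `band`, `row_lo`, `row_hi`, `control` (logical; one control
#'   band per lane) — [simulate_gel()] produces this format.
#' @param baseline `"flanking_median"` (default) or `"rolling_open"`.
#' @param bg_halfwidth half-width (rows) of the rolling-open baseline
#'   window; default = the largest annotated band-window height, which
#'   guarantees the window sees true background at band centers.
#' @return tibble of class `densitometry_result`, one row per non-control
#'   band: `lane`, `band`, `integral`, `control_integral`,
#'   `relative_intensity`.
#' @export
densitometry_ratio <- function(gel, annotations,
                               baseline = c("flanking_median", "rolling_open"),
                               bg_halfwidth = NULL) {
  stopifnot(is.matrix(gel),
            all(c("lane", "col_lo", "col_hi", "band", "row_lo", "row_hi",
                  "control") %in% names(annotations)))
  if (is.null(bg_halfwidth))
    bg_halfwidth <- max(annotations$row_hi - annotations$row_lo + 1L)
  baseline <- match.arg(baseline)
  out <- purrr::map_dfr(unique(annotations$lane), function(l) {
    ann <- annotations[annotations$lane == l, , drop = FALSE]
    prof <- rowSums(gel[, ann$col_lo[1]:ann$col_hi[1], drop = FALSE])
    base <- if (baseline == "flanking_median") {
      inband <- logical(length(prof))
      for (b in seq_len(nrow(ann))) inband[ann$row_lo[b]:ann$row_hi[b]] <- TRUE
      if (all(inband)) stop("lane ", l, ": band windows cover the whole lane; ",
                            "no background rows left", call. = FALSE)
      stats::median(prof[!inband])
    } else {
      .baseline_open(prof, bg_halfwidth)
    }
    corr <- pmax(prof - base, 0)
    integrals <- vapply(seq_len(nrow(ann)), function(b)
      sum(corr[ann$row_lo[b]:ann$row_hi[b]]), numeric(1))
    ctrl <- integrals[ann$control]
    if (length(ctrl) != 1 || ctrl <= 0)
      stop("lane ", l, ": loading-control integral is not positive after ",
           "background subtraction", call. = FALSE)
    tibble::tibble(lane = l, band = ann$band[!ann$control],
                   integral = integrals[!ann$control],
                   control_integral = ctrl,
                   relative_intensity = integrals[!ann$control] / ctrl)
  })
  class(out) <- c("densitometry_result", class(out))
  out
}

# rolling minimum with edge replication, half-width h
.rolling_min <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    min(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

.rolling_max <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    max(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

# morphological-opening baseline (the 1D analogue of rolling-ball background
# subtraction): rolling minimum then rolling maximum of a lightly smoothed
# profile. The smoothing and the max pass correct the downward bias a plain
# rolling minimum has on noisy profiles; the window must exceed the band
# half-width so the baseline reaches true background beside every band.
.baseline_open <- function(profile, halfwidth, smooth = 3L) {
  sm <- stats::filter(profile, rep(1 / smooth, smooth), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- profile[is.na(sm)]
  .rolling_max(.rolling_min(sm, halfwidth), halfwidth)
}
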