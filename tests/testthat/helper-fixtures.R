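# shared fixture builders; everything is generated in code at test time

# brute-force sliding-window median with edge replication; same footprint
# convention as median_denoise (di^2 + dj^2 <= r^2 + 1)
bf_median <- function(x, radius = 1) {
  h <- nrow(x); w <- ncol(x)
  r <- floor(radius + 1e-9)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2 + 1, ]
  out <- x
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- mapply(function(di, dj)
      x[min(max(i + di, 1), h), min(max(j + dj, 1), w)],
      offs$di, offs$dj)
    out[i, j] <- stats::median(vals)
  }
  out
}

# brute-force connected components (8-connectivity) by flood fill
bf_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  k <- 0L
  for (i0 in seq_len(h)) for (j0 in seq_len(w)) {
    if (mask[i0, j0] && lab[i0, j0] == 0L) {
      k <- k + 1L
      queue <- list(c(i0, j0)); lab[i0, j0] <- k
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          i <- p[1] + di; j <- p[2] + dj
          if (i >= 1 && i <= h && j >= 1 && j <= w &&
              mask[i, j] && lab[i, j] == 0L) {
            lab[i, j] <- k
            queue[[length(queue) + 1]] <- c(i, j)
          }
        }
      }
    }
  }
  lab
}

# binary disk mask fixture
disk <- function(h, w, crow, ccol, r) {
  outer((seq_len(h) - crow)^2, (seq_len(w) - ccol)^2, "+") <= r^2
}

# standard three-lane gel fixture with band/control ratios 0.5, 1, 2
gel_lanes_standard <- function() {
  list(
    data.frame(band = c("X", "ctrl"), position = c(80, 180),
               integral = c(1000, 2000), control = c(FALSE, TRUE)),
    data.frame(band = c("X", "ctrl"), position = c(80, 180),
               integral = c(2000, 2000), control = c(FALSE, TRUE)),
    data.frame(band = c("X", "ctrl"), position = c(80, 180),
               integral = c(4000, 2000), control = c(FALSE, TRUE)))
}

# full spheroid analysis chain used by several recovery tests
analyze_spheroid <- function(sim, segment_channel = "marker",
                             rim_width = NULL) {
  img <- sim$image
  mask <- spheroid_mask(img, "DAPI")
  lab <- gate_rois(multistep_segment(get_channel(img, segment_channel)), mask)
  tab <- region_properties(lab, img)
  if (is.null(rim_width)) rim_width <- auto_rim_width(tab)
  tab <- assign_zones(tab, rim_partition(mask, rim_width))
  bg <- estimate_background(img, mask, "marker")
  list(mask = mask, labels = lab, table = tab, background = bg)
}
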