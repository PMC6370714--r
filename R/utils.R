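#' Label connected components of a binary mask
#'
#' Foreground objects are 8-connected throughout the package (diagonal
#' neighbours belong to the same object), the convention of ImageJ's
#' particle analyzer. Labels are compact, 1..K, in raster order of first
#' occurrence (column-major, as matrices are stored in R).
#'
#' @param mask logical or 0/1 numeric matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer label matrix.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- .as_mask(mask)
  lab <- EBImage::bwlabel(m)            # 4-connected labelling
  lab <- matrix(as.integer(round(lab)), nrow(m), ncol(m))
  k <- max(lab)
  if (k == 0L) return(lab)
  if (connectivity == 8) {
    # union labels that touch diagonally
    h <- nrow(lab); w <- ncol(lab)
    a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal
    a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # down-left diagonal
    pick1 <- a1 > 0L & b1 > 0L & a1 != b1
    pick2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- rbind(cbind(a1[pick1], b1[pick1]), cbind(a2[pick2], b2[pick2]))
    if (nrow(pairs)) {
      parent <- seq_len(k)
      find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
      for (i in seq_len(nrow(pairs))) {
        ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(k), find, integer(1))
      lab[] <- c(0L, root)[lab + 1L]
    }
  }
  compact_labels(lab)
}

#' Renumber positive labels to 1..K preserving order of first occurrence
#' @param labelmap integer label matrix.
#' @return relabelled integer matrix.
#' @export
compact_labels <- function(labelmap) {
  v <- as.integer(labelmap)
  ids <- unique(v[v > 0L])
  if (length(ids) == 0L) {
    out <- matrix(0L, nrow(labelmap), ncol(labelmap))
    return(out)
  }
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- ifelse(v > 0L, map[pmax(v, 1L)], 0L)
  matrix(as.integer(out), nrow(labelmap), ncol(labelmap))
}

.as_mask <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  m
}

# --- histogram thresholds (256 bins over the observed range) ----------------

.hist256 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(NULL)
  centers <- lo + (seq_len(256) - 0.5) * (hi - lo) / 256
  idx <- pmin(pmax(floor((x - lo) / (hi - lo) * 256) + 1, 1), 256)
  counts <- tabulate(idx, nbins = 256)
  list(centers = centers, counts = counts)
}

# isodata: iterate t <- mean of the two class means until fixed point
.threshold_isodata <- function(x) {
  h <- .hist256(x)
  if (is.null(h)) return(max(x))
  t <- sum(h$centers * h$counts) / sum(h$counts)
  for (it in 1:200) {
    below <- h$centers <= t
    n1 <- sum(h$counts[below]); n2 <- sum(h$counts[!below])
    m1 <- if (n1 > 0) sum(h$centers[below] * h$counts[below]) / n1 else min(h$centers)
    m2 <- if (n2 > 0) sum(h$centers[!below] * h$counts[!below]) / n2 else max(h$centers)
    tn <- (m1 + m2) / 2
    if (abs(tn - t) < 1e-9 * (max(x) - min(x) + 1e-12)) break
    t <- tn
  }
  t
}

# otsu: maximize between-class variance over bin boundaries
.threshold_otsu <- function(x) {
  h <- .hist256(x)
  if (is.null(h)) return(max(x))
  p <- h$counts / sum(h$counts)
  omega <- cumsum(p)
  mu <- cumsum(p * h$centers)
  mu_t <- mu[256]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  h$centers[which.max(sigma_b)]
}

.threshold_mean <- function(x) mean(x)

#' Greedy one-to-one matching of detected objects to ground-truth cells
#'
#' Candidate pairs within `max_dist` (Euclidean, pixels) are assigned
#' greedily in order of increasing distance, each truth cell and each
#' detection used at most once. The standard detection metrics follow:
#' recall = matched / n_truth, precision = matched / n_detected.
#'
#' @param truth data frame with columns `row`, `col` (true cell centers).
#' @param detected data frame with columns `centroid_row`, `centroid_col`
#'   (for example a [region_properties()] table).
#' @param max_dist maximal center-to-centroid distance for a match.
#' @return list with `n_truth`, `n_detected`, `n_matched`, `recall`,
#'   `precision`, and `matches` (tibble of truth/detected index pairs).
#' @export
match_cells <- function(truth, detected, max_dist) {
  nt <- nrow(truth); nd <- nrow(detected)
  if (nt == 0L || nd == 0L) {
    return(list(n_truth = nt, n_detected = nd, n_matched = 0L,
                recall = if (nt) 0 else NA_real_,
                precision = if (nd) 0 else NA_real_,
                matches = tibble::tibble(truth = integer(), detected = integer())))
  }
  dmat <- outer(truth$row, detected$centroid_row, "-")^2 +
    outer(truth$col, detected$centroid_col, "-")^2
  cand <- which(dmat <= max_dist^2, arr.ind = TRUE)
  used_t <- logical(nt); used_d <- logical(nd)
  mt <- integer(0); md <- integer(0)
  if (nrow(cand)) {
    ord <- order(dmat[cand])
    cand <- cand[ord, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      ti <- cand[i, 1]; di <- cand[i, 2]
      if (!used_t[ti] && !used_d[di]) {
        used_t[ti] <- TRUE; used_d[di] <- TRUE
        mt <- c(mt, ti); md <- c(md, di)
      }
    }
  }
  list(n_truth = nt, n_detected = nd, n_matched = length(mt),
       recall = length(mt) / nt, precision = length(mt) / nd,
       matches = tibble::tibble(truth = mt, detected = md))
}

# clamp helper
.clip01 <- function(x) pmin(pmax(x, 0), 1)
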