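#' Parameters of the centroid-recovery procedure
#'
#' Note that `sigma` is the *variance* of the Gaussian smoothing filter (in
#' squared pixels); the filter's standard deviation is `sqrt(sigma)`. The
#' remaining constants are fixed properties of the procedure: local maxima
#' are sought over 7x7 neighbourhoods, maxima within 7 px of the border are
#' discarded, maxima closer than 8 px are merged, and an image counts as
#' densely populated above 0.0011 cones per pixel.
#'
#' @param sigma Gaussian filter variance in px^2, `> 0`.
#' @param threshold probability threshold `T` in `[0, 1]`; smoothed maxima
#'   below it are rejected.
#' @param maxima_window,border_margin,merge_distance,density_cutoff fixed
#'   procedure constants (see above); exposed for completeness.
#' @return list of class `recovery_params`.
#' @export
recovery_params <- function(sigma, threshold, maxima_window = 7L,
                            border_margin = 7L, merge_distance = 8,
                            density_cutoff = 0.0011) {
  stopifnot(sigma > 0, threshold >= 0, threshold <= 1,
            maxima_window %% 2 == 1)
  structure(list(sigma = sigma, threshold = threshold,
                 maxima_window = as.integer(maxima_window),
                 border_margin = as.integer(border_margin),
                 merge_distance = merge_distance,
                 density_cutoff = density_cutoff),
            class = "recovery_params")
}

# Sliding-window maximum of a matrix over a centred win x win neighbourhood
# (values outside the image ignored), computed by shift-and-max.
.window_max <- function(m, win) {
  r <- (win - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  out <- matrix(-Inf, h, w)
  for (di in -r:r) {
    ri <- max(1, 1 + di):min(h, h + di)
    src_r <- ri - di
    for (dj in -r:r) {
      ci <- max(1, 1 + dj):min(w, w + dj)
      out[ri, ci] <- pmax(out[ri, ci], m[src_r, ci - dj])
    }
  }
  out
}

# Single-linkage merge of points closer than merge_distance: clusters of the
# "< d" graph are replaced by their mean, iterated until all pairwise
# distances are >= d.
.merge_close <- function(pts, d) {
  repeat {
    n <- nrow(pts)
    if (n < 2) return(pts)
    dm <- as.matrix(stats::dist(pts))
    close <- dm < d & upper.tri(dm)
    if (!any(close)) return(pts)
    comp <- seq_len(n)  # union-find on the "close" graph
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (e in which(close)) {
      i <- as.integer((e - 1L) %% n + 1L); j <- as.integer((e - 1L) %/% n + 1L)
      ri <- find(i); rj <- find(j)
      if (ri != rj) comp[rj] <- ri
    }
    roots <- vapply(seq_len(n), find, numeric(1))
    pts <- do.call(rbind, lapply(unique(roots), function(rt)
      colMeans(pts[roots == rt, , drop = FALSE])))
  }
}

#' Recover cone centroids from a cone-probability map
#'
#' Applies, in order: (1) Gaussian smoothing with filter variance
#' `params$sigma`; (2) local-maximum detection over centred
#' `maxima_window`-square neighbourhoods (a pixel qualifies iff its smoothed
#' value is at least every value in its window; on exact ties the
#' topmost-then-leftmost pixel of the plateau wins); (3) rejection of maxima
#' whose smoothed value is below `threshold`; (4) rejection of maxima within
#' `border_margin` pixels of the image border; (5) single-linkage merging of
#' maxima closer than `merge_distance` into their mean position, iterated
#' until all pairwise distances reach `merge_distance`.
#'
#' @param prob `h x w` matrix of cone probabilities in `[0, 1]` (the cone
#'   channel of [forward()]).
#' @param params a [recovery_params()].
#' @return numeric matrix with columns `row`, `col` (0-based, sub-pixel);
#'   zero rows when nothing survives.
#' @export
recover_centroids <- function(prob, params) {
  stopifnot(is.matrix(prob), inherits(params, "recovery_params"))
  if (any(prob < -1e-9) || any(prob > 1 + 1e-9))
    stop("probability map values must lie in [0, 1]")
  h <- nrow(prob); w <- ncol(prob)
  s <- gaussian_smooth(prob, sqrt(params$sigma))
  wm <- .window_max(s, params$maxima_window)
  cand <- which(s >= wm, arr.ind = TRUE)  # 1-based (row, col)
  if (nrow(cand)) {
    # resolve exact ties: drop a candidate if an equal-valued pixel earlier
    # in (row, col) order lies inside its window
    r <- (params$maxima_window - 1L) %/% 2L
    keep <- rep(TRUE, nrow(cand))
    ord <- order(cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    for (a in seq_len(nrow(cand))) {
      i <- cand[a, 1]; j <- cand[a, 2]; v <- s[i, j]
      win <- s[max(1, i - r):min(h, i + r), max(1, j - r):min(w, j + r)]
      eq <- which(win == v, arr.ind = TRUE)
      eq[, 1] <- eq[, 1] + max(1, i - r) - 1
      eq[, 2] <- eq[, 2] + max(1, j - r) - 1
      first <- eq[order(eq[, 1], eq[, 2])[1], ]
      if (!(first[1] == i && first[2] == j)) keep[a] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  if (nrow(cand)) cand <- cand[s[cand] >= params$threshold, , drop = FALSE]
  if (nrow(cand)) {
    r0 <- cand[, 1] - 1; c0 <- cand[, 2] - 1  # to 0-based
    b <- params$border_margin
    ok <- r0 >= b & r0 <= h - 1 - b & c0 >= b & c0 <= w - 1 - b
    cand <- cbind(row = r0[ok], col = c0[ok])
  } else {
    cand <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  }
  pts <- .merge_close(cand, params$merge_distance)
  pts <- matrix(pts, ncol = 2, dimnames = list(NULL, c("row", "col")))
  pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
}

#' Classify an image as densely or sparsely populated
#'
#' Densely populated means strictly more than `cutoff` (default 0.0011)
#' cones per pixel — the dense/sparse switch of the adaptive localiser.
#'
#' @param centroids centroid matrix (or anything with a row count).
#' @param shape `c(height, width)` of the image.
#' @param cutoff cones-per-pixel cut-off.
#' @return `"dense"` or `"sparse"`.
#' @export
classify_density <- function(centroids, shape, cutoff = 0.0011) {
  n <- nrow(as_centroids(centroids))
  if (n / (shape[1] * shape[2]) > cutoff) "dense" else "sparse"
}

#' Adaptive two-pass centroid localisation
#'
#' First recovers centroids with the jointly calibrated parameters
#' `params_b` to decide whether the image is densely or sparsely populated,
#' then re-runs recovery with the regime-specific parameters (`params_h`
#' for dense, `params_s` for sparse) and returns that second-pass set.
#'
#' @param prob `h x w` cone-probability matrix.
#' @param params_b,params_h,params_s calibrated [recovery_params()] for
#'   both/healthy(dense)/sparse image populations.
#' @return centroid matrix with attribute `regime` (`"dense"`/`"sparse"`).
#' @export
adaptive_localise <- function(prob, params_b, params_h, params_s) {
  first <- recover_centroids(prob, params_b)
  regime <- classify_density(first, dim(prob), params_b$density_cutoff)
  out <- recover_centroids(prob,
                           if (regime == "dense") params_h else params_s)
  attr(out, "regime") <- regime
  out
}

#' Calibrate recovery parameters on a validation set
#'
#' Grid search over (sigma, threshold) maximising the mean matching Dice
#' score between recovered and ground-truth centroids over the validation
#' images. Ties are broken toward the smallest sigma, then the smallest
#' threshold.
#'
#' @param prob_maps list of `h x w` cone-probability matrices.
#' @param truths list of ground-truth centroid matrices (same length).
#' @param sigmas candidate filter variances (px^2).
#' @param thresholds candidate probability thresholds.
#' @return a [recovery_params()] with attributes `dice` (the achieved mean
#'   Dice) and `grid` (the full search table).
#' @export
calibrate <- function(prob_maps, truths,
                      sigmas = c(0.5, 1, 2, 4, 8, 16),
                      thresholds = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(length(prob_maps) >= 1, length(prob_maps) == length(truths))
  grid <- expand.grid(sigma = sigmas, threshold = thresholds,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$sigma, grid$threshold), ]
  grid$dice <- NA_real_
  best <- -Inf; best_row <- 1L
  for (g in seq_len(nrow(grid))) {
    rp <- recovery_params(grid$sigma[g], grid$threshold[g])
    d <- vapply(seq_along(prob_maps), function(i) {
      est <- recover_centroids(prob_maps[[i]], rp)
      .safe_dice(est, truths[[i]])
    }, numeric(1))
    grid$dice[g] <- mean(d)
    if (grid$dice[g] > best) { best <- grid$dice[g]; best_row <- g }
  }
  out <- recovery_params(grid$sigma[best_row], grid$threshold[best_row])
  attr(out, "dice") <- best
  attr(out, "grid") <- grid
  out
}

# Matching Dice that tolerates empty sets: both empty -> 1, one empty -> 0.
.safe_dice <- function(est, truth) {
  est <- as_centroids(est); truth <- as_centroids(truth)
  if (nrow(est) == 0 && nrow(truth) == 0) return(1)
  if (nrow(est) == 0 || nrow(truth) == 0) return(0)
  dice(match_centroids(est, truth))
}
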