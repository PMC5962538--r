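#' Median nearest-neighbour cone spacing
#'
#' The median, over ground-truth centroids, of each point's Euclidean
#' distance to its nearest neighbour. This per-image spacing sets the
#' matching tolerance `min(0.75 * d, 20)`.
#'
#' @param truth centroid matrix with at least two points.
#' @return median spacing `d` in pixels.
#' @export
median_spacing <- function(truth) {
  truth <- as_centroids(truth)
  if (nrow(truth) < 2) stop("median spacing needs at least two centroids")
  dm <- as.matrix(stats::dist(truth))
  diag(dm) <- Inf
  stats::median(apply(dm, 1, min))
}

#' Match estimated centroids to ground truth
#'
#' One-to-one greedy matching: all (estimate, truth) pairs within the
#' tolerance are sorted by ascending distance (ties broken by truth index,
#' then estimate index) and accepted greedily whenever both endpoints are
#' still unmatched. The tolerance defaults to `min(0.75 * d, 20)` pixels
#' with `d` the median nearest-neighbour spacing of the truth set; with
#' fewer than two truth points it falls back to the 20 px cap (spacing is
#' undefined, and sparse diseased mosaics are exactly where the cap
#' matters).
#'
#' @param est,truth centroid matrices (columns `row`, `col`).
#' @param tolerance optional matching radius in pixels; computed from
#'   `truth` when `NULL`.
#' @return list of class `match_result` with counts `tp`, `fp`, `fn`, the
#'   matched `pairs` (columns `est`, `truth`, `distance`; 1-based indices)
#'   and the `tolerance` used.
#' @export
match_centroids <- function(est, truth, tolerance = NULL) {
  est <- as_centroids(est); truth <- as_centroids(truth)
  if (is.null(tolerance)) {
    tolerance <- if (nrow(truth) >= 2) min(0.75 * median_spacing(truth), 20)
                 else 20
  }
  ne <- nrow(est); nt <- nrow(truth)
  pairs <- matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("est", "truth", "distance")))
  if (ne && nt) {
    dmat <- outer(est[, 1], truth[, 1], "-")^2 +
      outer(est[, 2], truth[, 2], "-")^2
    dmat <- sqrt(dmat)
    idx <- which(dmat <= tolerance, arr.ind = TRUE)
    if (nrow(idx)) {
      cand <- data.frame(est = idx[, 1], truth = idx[, 2],
                         distance = dmat[idx])
      cand <- cand[order(cand$distance, cand$truth, cand$est), ]
      used_e <- logical(ne); used_t <- logical(nt)
      for (ci in seq_len(nrow(cand))) {
        e <- cand$est[ci]; t <- cand$truth[ci]
        if (!used_e[e] && !used_t[t]) {
          used_e[e] <- TRUE; used_t[t] <- TRUE
          pairs <- rbind(pairs, as.matrix(cand[ci, ]))
        }
      }
    }
  }
  tp <- nrow(pairs)
  structure(list(tp = tp, fp = ne - tp, fn = nt - tp, pairs = pairs,
                 tolerance = tolerance),
            class = "match_result")
}

#' Dice coefficient of a matching result
#'
#' `Dice = 2 TP / (2 TP + FP + FN)` over matched/unmatched detection
#' counts.
#'
#' @param result a [match_centroids()] result, or a list with `tp`, `fp`,
#'   `fn`.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(result) {
  with(result, {
    if (tp + fp + fn == 0)
      stop("Dice undefined: no estimates and no truth centroids")
    2 * tp / (2 * tp + fp + fn)
  })
}

#' Bland-Altman agreement statistics for cone counts
#'
#' For per-image count pairs, analyses the differences
#' `delta = estimated - truth`: the mean difference with its 95% t-based
#' confidence interval, and the limits of agreement
#' `mean(delta) +/- 1.96 * sd(delta)`, each with the standard 95%
#' confidence half-width `1.96 * sd * sqrt(3 / n)`.
#'
#' @param est_counts,truth_counts numeric vectors of per-image cone counts
#'   (at least 3 images).
#' @return list of class `bland_altman` with `mean_diff`, `mean_ci`
#'   (half-width), `sd_diff`, `uloa`, `lloa`, `loa_ci` (half-width), `n`.
#' @export
bland_altman <- function(est_counts, truth_counts) {
  stopifnot(length(est_counts) == length(truth_counts))
  n <- length(est_counts)
  if (n < 3) stop("Bland-Altman analysis needs at least 3 count pairs")
  delta <- est_counts - truth_counts
  m <- mean(delta); s <- stats::sd(delta)
  structure(list(mean_diff = m,
                 mean_ci = stats::qt(0.975, n - 1) * s / sqrt(n),
                 sd_diff = s,
                 uloa = m + 1.96 * s,
                 lloa = m - 1.96 * s,
                 loa_ci = 1.96 * s * sqrt(3 / n),
                 n = n),
            class = "bland_altman")
}

#' Evaluate a batch of centroid estimates
#'
#' Convenience wrapper: matches every estimate/truth pair, reports
#' per-image Dice and counts, and aggregates (mean and sd of Dice, plus
#' Bland-Altman agreement of the counts when at least 3 images are given).
#' Images with truth but an empty estimate score Dice 0; images with
#' neither are flagged and score 1.
#'
#' @param ests,truths lists of centroid matrices of equal length.
#' @return list with `per_image` (data frame) and `summary`.
#' @export
evaluate_batch <- function(ests, truths) {
  stopifnot(length(ests) == length(truths))
  per <- do.call(rbind, lapply(seq_along(ests), function(i) {
    e <- as_centroids(ests[[i]]); t <- as_centroids(truths[[i]])
    if (nrow(t) == 0 && nrow(e) == 0)
      return(data.frame(image = i, tp = 0, fp = 0, fn = 0, dice = 1,
                        est_count = 0, truth_count = 0, degenerate = TRUE))
    mr <- match_centroids(e, t)
    data.frame(image = i, tp = mr$tp, fp = mr$fp, fn = mr$fn,
               dice = dice(mr), est_count = nrow(e), truth_count = nrow(t),
               degenerate = FALSE)
  }))
  summary <- list(mean_dice = mean(per$dice), sd_dice = stats::sd(per$dice),
                  n = nrow(per))
  if (nrow(per) >= 3)
    summary$agreement <- bland_altman(per$est_count, per$truth_count)
  list(per_image = per, summary = summary)
}
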