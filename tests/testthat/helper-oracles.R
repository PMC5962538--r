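# Independent reference implementations used as test oracles. These are
# deliberately naive (per-pixel recursion, literal rule application, full
# enumeration) and share no code with the fast paths they check.

sigmoid_ref <- function(x) 1 / (1 + exp(-x))

# Naive per-pixel 2D LSTM recursion in the canonical scan order
# (top-to-bottom, left-to-right), double loop, no vectorisation.
naive_block_scan <- function(x, wts, direction = 0L) {
  x <- rot_image(x, direction)
  d <- dim(x); h <- d[1]; w <- d[2]; u <- wts$u
  H <- array(0, c(h, w, u)); C <- array(0, c(h, w, u))
  for (i in 1:h) for (j in 1:w) {
    hu <- if (i > 1) H[i - 1, j, ] else rep(0, u)
    hl <- if (j > 1) H[i, j - 1, ] else rep(0, u)
    cu <- if (i > 1) C[i - 1, j, ] else rep(0, u)
    cl <- if (j > 1) C[i, j - 1, ] else rep(0, u)
    a <- wts$win %*% x[i, j, ] + wts$rup %*% hu + wts$rleft %*% hl + wts$bias
    gi <- sigmoid_ref(a[1:u])
    f1 <- sigmoid_ref(a[u + (1:u)])
    f2 <- sigmoid_ref(a[2 * u + (1:u)])
    go <- sigmoid_ref(a[3 * u + (1:u)])
    gg <- tanh(a[4 * u + (1:u)])
    cc <- gi * gg + 0.5 * f1 * cu + 0.5 * f2 * cl
    C[i, j, ] <- cc
    H[i, j, ] <- go * tanh(cc)
  }
  rot_image(H, -direction)
}

# Literal application of the five centroid-recovery rules by enumeration.
brute_recover <- function(prob, params) {
  h <- nrow(prob); w <- ncol(prob)
  s <- gaussian_smooth(prob, sqrt(params$sigma))
  r <- (params$maxima_window - 1) %/% 2
  pts <- NULL
  for (i in 1:h) for (j in 1:w) {
    win_r <- max(1, i - r):min(h, i + r)
    win_c <- max(1, j - r):min(w, j + r)
    win <- s[win_r, win_c, drop = FALSE]
    if (s[i, j] < max(win)) next
    # plateau tie-break: topmost-then-leftmost equal-valued pixel in window
    eq <- which(win == s[i, j], arr.ind = TRUE)
    eq <- cbind(eq[, 1] + win_r[1] - 1, eq[, 2] + win_c[1] - 1)
    eq <- eq[order(eq[, 1], eq[, 2]), , drop = FALSE]
    if (!(eq[1, 1] == i && eq[1, 2] == j)) next
    if (s[i, j] < params$threshold) next
    r0 <- i - 1; c0 <- j - 1
    b <- params$border_margin
    if (r0 < b || r0 > h - 1 - b || c0 < b || c0 > w - 1 - b) next
    pts <- rbind(pts, c(r0, c0))
  }
  if (is.null(pts)) pts <- matrix(numeric(0), 0, 2)
  # single-linkage merge, iterated to convergence
  repeat {
    n <- nrow(pts)
    if (n < 2) break
    dm <- as.matrix(dist(pts)); diag(dm) <- Inf
    if (min(dm) >= params$merge_distance) break
    comp <- seq_len(n)
    for (a in 1:(n - 1)) for (b2 in (a + 1):n) if (dm[a, b2] < params$merge_distance) {
      old <- comp[b2]; comp[comp == old] <- comp[a]
    }
    pts <- do.call(rbind, lapply(unique(comp), function(cc)
      colMeans(pts[comp == cc, , drop = FALSE])))
  }
  pts <- matrix(pts, ncol = 2, dimnames = list(NULL, c("row", "col")))
  pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
}

# Greedy-by-distance one-to-one matcher by full pair enumeration.
brute_match <- function(est, truth, tolerance) {
  ne <- nrow(est); nt <- nrow(truth)
  cand <- NULL
  for (e in seq_len(ne)) for (t in seq_len(nt)) {
    d <- sqrt(sum((est[e, ] - truth[t, ])^2))
    if (d <= tolerance) cand <- rbind(cand, c(e, t, d))
  }
  tp <- 0; used_e <- logical(ne); used_t <- logical(nt); pairs <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(cand[, 3], cand[, 2], cand[, 1]), , drop = FALSE]
    for (ci in seq_len(nrow(cand))) {
      e <- cand[ci, 1]; t <- cand[ci, 2]
      if (!used_e[e] && !used_t[t]) {
        used_e[e] <- TRUE; used_t[t] <- TRUE
        tp <- tp + 1
        pairs <- rbind(pairs, cand[ci, ])
      }
    }
  }
  list(tp = tp, fp = ne - tp, fn = nt - tp, pairs = pairs)
}

# Tiny helper: random centroid matrix inside a frame.
random_points <- function(n, h, w) {
  cbind(row = runif(n, 0, h - 1), col = runif(n, 0, w - 1))
}
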