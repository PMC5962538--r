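#' @useDynLib conefinder, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Gate order used throughout the stacked weight matrices: i, f1, f2, o, g.
.GATES <- c("i", "f1", "f2", "o", "g")

#' Construct the weights of one directional MDLSTM block
#'
#' A 2D MDLSTM block maps a `k`-channel feature image to a `u`-channel one by
#' scanning pixels in a fixed order. Each gate (input `i`, two forget gates
#' `f1`/`f2` for the two incoming scan directions, output `o`) and the cell
#' candidate `g` has one input-weight matrix (`u x k`), two recurrent
#' matrices (`u x u`, one per predecessor), and a bias. The five input
#' matrices are stacked row-wise into `win` (`5u x k`), the recurrent
#' matrices per predecessor into `rup` and `rleft` (`5u x u`), and the biases
#' into `bias` (length `5u`), in gate order i, f1, f2, o, g.
#'
#' @param u number of units (output channels), `>= 1`.
#' @param k number of input channels, `>= 1`.
#' @param win,rup,rleft,bias stacked parameter arrays as described above;
#'   defaults are all-zero (useful for shape plumbing and tests).
#' @return an object of class `block_weights`.
#' @export
block_weights <- function(u, k,
                          win = matrix(0, 5 * u, k),
                          rup = matrix(0, 5 * u, u),
                          rleft = matrix(0, 5 * u, u),
                          bias = numeric(5 * u)) {
  stopifnot(u >= 1, k >= 1)
  win <- as.matrix(win); rup <- as.matrix(rup); rleft <- as.matrix(rleft)
  if (!identical(dim(win), as.integer(c(5 * u, k))))
    stop("win must be (5u) x k")
  if (!identical(dim(rup), as.integer(c(5 * u, u))) ||
      !identical(dim(rleft), as.integer(c(5 * u, u))))
    stop("rup and rleft must be (5u) x u")
  if (length(bias) != 5 * u) stop("bias must have length 5u")
  if (!all(is.finite(win), is.finite(rup), is.finite(rleft),
           is.finite(bias)))
    stop("block weights must be finite")
  structure(list(u = as.integer(u), k = as.integer(k), win = win,
                 rup = rup, rleft = rleft, bias = as.numeric(bias)),
            class = "block_weights")
}

#' Random block weights from the network's initialisation distribution
#'
#' All gate and candidate weights are drawn i.i.d. Gaussian with mean 0 and
#' standard deviation `sd`; biases start at zero.
#'
#' @inheritParams block_weights
#' @param sd standard deviation of the Gaussian initialiser.
#' @return a `block_weights` object.
#' @export
init_block_weights <- function(u, k, sd = 0.25) {
  block_weights(u, k,
                win = matrix(stats::rnorm(5 * u * k, 0, sd), 5 * u, k),
                rup = matrix(stats::rnorm(5 * u * u, 0, sd), 5 * u, u),
                rleft = matrix(stats::rnorm(5 * u * u, 0, sd), 5 * u, u))
}

# Coerce a 2D matrix to an h x w x 1 feature image.
as_feature_image <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("feature image must be h x w x k")
  x
}

#' Rotate a feature image by multiples of 90 degrees
#'
#' Counter-clockwise rotation applied channel-wise; `k` is taken modulo 4.
#' Used to realise the four MDLSTM scan directions by rotating the image,
#' scanning in the canonical order, and rotating the activations back.
#'
#' @param x `h x w x k` array (or `h x w` matrix).
#' @param k number of 90-degree counter-clockwise rotations.
#' @return rotated array.
#' @export
rot_image <- function(x, k) {
  x <- as_feature_image(x)
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(x)
  rot1 <- function(m) {
    m <- t(m)
    m[rev(seq_len(nrow(m))), , drop = FALSE]
  }
  for (r in seq_len(k)) {
    d <- dim(x)
    out <- array(0, c(d[2], d[1], d[3]))
    for (ch in seq_len(d[3]))
      out[, , ch] <- rot1(matrix(x[, , ch], d[1], d[2]))
    x <- out
  }
  x
}

# Internal: canonical-direction forward with optional cache for backprop.
# X is h x w x k; returns H as u x (h*w) plus the C++ cache.
.block_forward_raw <- function(x, wts, keep_cache = FALSE) {
  d <- dim(x)
  xm <- t(matrix(x, d[1] * d[2], d[3]))  # k x (h*w), pixel-major
  out <- mdlstm_forward_cpp(xm, d[1], d[2], wts$win, wts$rup, wts$rleft,
                            wts$bias, keep_cache)
  out$h <- d[1]; out$w <- d[2]; out$X <- xm
  out
}

#' Directional MDLSTM block scan
#'
#' Applies one MDLSTM block to a feature image along one of the four scan
#' directions. The image is rotated `direction` times by 90 degrees, scanned
#' in the canonical top-to-bottom left-to-right order (each pixel sees its
#' upper and left predecessors; missing neighbours contribute zero), and the
#' resulting activations are rotated back into the original frame. The cell
#' state uses the bounded update `c = i*g + (f1*c_up + f2*c_left)/2`, which
#' keeps the sum of the forget coefficients at or below one so the cell
#' cannot grow geometrically along the scan.
#'
#' @param image `h x w x k` feature image (a plain `h x w` matrix is treated
#'   as single-channel).
#' @param weights a [block_weights()] object with matching `k`.
#' @param direction integer 0-3: number of 90-degree rotations applied before
#'   the canonical scan.
#' @return `h x w x u` array of activations, with attribute `max_abs_cell`,
#'   the largest absolute cell state encountered (diagnostic for the
#'   bounded-state property).
#' @export
block_scan <- function(image, weights, direction = 0L) {
  stopifnot(inherits(weights, "block_weights"))
  x <- as_feature_image(image)
  if (dim(x)[3] != weights$k)
    stop("image has ", dim(x)[3], " channels, weights expect ", weights$k)
  if (!all(is.finite(x))) stop("non-finite values in input image")
  xr <- rot_image(x, direction)
  out <- .block_forward_raw(xr, weights, keep_cache = FALSE)
  hr <- array(t(out$H), c(out$h, out$w, weights$u))
  res <- rot_image(hr, -direction)
  attr(res, "max_abs_cell") <- out$Cmax
  res
}

#' Four-direction MDLSTM layer
#'
#' Runs four distinct MDLSTM blocks over the image, one per scan direction
#' (0-3 quarter-turns), and concatenates their activations along channels in
#' fixed direction order. After one layer every pixel's feature vector has
#' accumulated context from the whole image.
#'
#' @param image `h x w x k` feature image.
#' @param weights4 list of four [block_weights()], all with the same `u` and
#'   `k`; element `d+1` serves direction `d`.
#' @return `h x w x 4u` array.
#' @export
layer_scan <- function(image, weights4) {
  stopifnot(length(weights4) == 4)
  us <- vapply(weights4, function(w) w$u, integer(1))
  if (length(unique(us)) != 1) stop("all four blocks must share u")
  slabs <- lapply(0:3, function(d) block_scan(image, weights4[[d + 1]], d))
  x <- as_feature_image(image)
  out <- array(0, c(dim(x)[1], dim(x)[2], 4 * us[1]))
  for (d in 0:3) out[, , (d * us[1] + 1):((d + 1) * us[1])] <- slabs[[d + 1]]
  out
}

#' Per-pixel multiplication count of one MDLSTM block application
#'
#' Counts the scalar multiplications needed to apply a `u`-unit block with
#' `k` input channels to one pixel: five input matrix-vector products
#' (`5uk`), ten recurrent matrix-vector products (`10u^2`), and six
#' element-wise products per unit (`i*g`; halving and applying each forget
#' gate to its predecessor cell; `o*tanh(c)`), i.e. `5uk + 10u^2 + 6u`.
#' Aggregating a 128-channel MDLSTM output down to one channel with a
#' convolution before the next MDLSTM layer is what makes the deep stack
#' affordable: compare `count_block_multiplications(32, 1)` with
#' `count_block_multiplications(32, 128)`.
#'
#' @param u number of units.
#' @param k number of input channels.
#' @return integer multiplication count.
#' @export
count_block_multiplications <- function(u, k) {
  stopifnot(u >= 1, k >= 1)
  as.integer(5 * u * k + 10 * u^2 + 6 * u)
}

# ---- internal training-path forward/backward (direction-aware) -------------

# Forward with cache. Returns list(h = h x w x u array, cache).
.block_forward_train <- function(x, wts, direction) {
  xr <- rot_image(x, direction)
  out <- .block_forward_raw(xr, wts, keep_cache = TRUE)
  hr <- array(t(out$H), c(out$h, out$w, wts$u))
  list(h = rot_image(hr, -direction),
       cache = list(raw = out, direction = direction, wts = wts))
}

# Backward: dh is h x w x u in the original frame. Returns weight gradients
# (stacked form) and dX (h x w x k in the original frame).
.block_backward_train <- function(dh, cache) {
  wts <- cache$wts; raw <- cache$raw
  dhr <- rot_image(dh, cache$direction)
  dH <- t(matrix(dhr, raw$h * raw$w, wts$u))
  gr <- mdlstm_backward_cpp(dH, raw$h, raw$w, raw$X, wts$win, wts$rup,
                            wts$rleft, raw$cache$G, raw$cache$C,
                            raw$cache$Tc, raw$H)
  dxr <- array(t(gr$dX), c(raw$h, raw$w, wts$k))
  list(win = gr$dWin, rup = gr$dRup, rleft = gr$dRleft,
       bias = as.numeric(gr$dbias), dx = rot_image(dxr, -cache$direction))
}
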