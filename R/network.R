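#' Initialise the segmentation network parameters
#'
#' Builds the parameter set of the cone-segmentation network: a 3x3
#' convolution (1 to 1 channel, tanh), a four-direction MDLSTM layer, a 3x3
#' convolution aggregating the `4u` MDLSTM channels back to 1 (tanh), a
#' second MDLSTM layer, then a per-pixel fully connected head
#' (`4u -> fc_hidden -> 2`) and softmax over the two classes
#' (background, cone).
#'
#' MDLSTM weights are sampled from a zero-mean Gaussian with standard
#' deviation `mdlstm_sd`; convolutional filters and fully connected weights
#' are sampled uniformly on `[-conv_range, conv_range]`; all biases start at
#' zero. Small initial weights matter here: large ones make the recurrent
#' gradients explode, while the bounded cell update tolerates small ones
#' well.
#'
#' @param seed integer seed for reproducible initialisation.
#' @param units MDLSTM units per directional block (32 in the reference
#'   architecture; smaller values give a faster, smaller network).
#' @param fc_hidden hidden width of the fully connected head.
#' @param mdlstm_sd standard deviation of the Gaussian MDLSTM initialiser.
#' @param conv_range half-width of the uniform initialiser for
#'   convolutional and fully connected weights.
#' @return an object of class `network_params`.
#' @export
init_params <- function(seed = 1L, units = 32L, fc_hidden = 64L,
                        mdlstm_sd = 0.25, conv_range = 0.1) {
  set.seed(seed)
  u <- as.integer(units)
  runifw <- function(n) stats::runif(n, -conv_range, conv_range)
  p <- list(
    conv1 = list(W = array(runifw(9), c(3, 3, 1, 1)), b = 0),
    mdlstm1 = lapply(1:4, function(d) init_block_weights(u, 1L, mdlstm_sd)),
    conv2 = list(W = array(runifw(9 * 4 * u), c(3, 3, 4 * u, 1)), b = 0),
    mdlstm2 = lapply(1:4, function(d) init_block_weights(u, 1L, mdlstm_sd)),
    fc_hidden = list(W = matrix(runifw(4 * u * fc_hidden), 4 * u, fc_hidden),
                     b = numeric(fc_hidden)),
    fc_out = list(W = matrix(runifw(fc_hidden * 2), fc_hidden, 2),
                  b = numeric(2)),
    meta = list(units = u, fc_hidden = as.integer(fc_hidden),
                mdlstm_sd = mdlstm_sd, conv_range = conv_range,
                seed = as.integer(seed),
                class_order = c("background", "cone"))
  )
  structure(p, class = "network_params")
}

.conv_forward <- function(x, layer) {
  conv3x3_forward_cpp(as_feature_image(x), as.numeric(layer$W),
                      as.numeric(layer$b))
}

# Forward pass with optional cache of every intermediate needed by backward.
.network_forward <- function(image, params, keep_cache = FALSE) {
  if (length(dim(image)) == 2L) image <- as_feature_image(image)
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 1L)
  if (!all(is.finite(image))) stop("non-finite values in input image")
  h <- dim(image)[1]; w <- dim(image)[2]
  u <- params$meta$units

  a1 <- .conv_forward(image, params$conv1)                    # h x w x 1
  m1 <- lapply(0:3, function(d)
    .block_forward_train(a1, params$mdlstm1[[d + 1]], d))
  f1 <- array(0, c(h, w, 4 * u))
  for (d in 0:3) f1[, , (d * u + 1):((d + 1) * u)] <- m1[[d + 1]]$h

  a2 <- .conv_forward(f1, params$conv2)                       # h x w x 1
  m2 <- lapply(0:3, function(d)
    .block_forward_train(a2, params$mdlstm2[[d + 1]], d))
  f2 <- array(0, c(h, w, 4 * u))
  for (d in 0:3) f2[, , (d * u + 1):((d + 1) * u)] <- m2[[d + 1]]$h

  Xf <- matrix(f2, h * w, 4 * u)                              # (hw) x 4u
  Z1 <- sweep(Xf %*% params$fc_hidden$W, 2, params$fc_hidden$b, "+")
  R1 <- pmax(Z1, 0)                                           # ReLU
  Z2 <- sweep(R1 %*% params$fc_out$W, 2, params$fc_out$b, "+")
  Z2 <- Z2 - apply(Z2, 1, max)                                # stable softmax
  E <- exp(Z2)
  P <- E / rowSums(E)                                         # (hw) x 2

  prob <- array(P, c(h, w, 2))
  if (!keep_cache) return(prob)
  list(prob = prob,
       cache = list(image = image, a1 = a1, m1 = m1, f1 = f1, a2 = a2,
                    m2 = m2, Xf = Xf, R1 = R1, P = P, h = h, w = w))
}

#' Segment an image into cone / background probabilities
#'
#' Runs the full network on a single-channel image of arbitrary size
#' (at least 8x8). Because MDLSTM scans and 3x3 convolutions are defined for
#' any grid, the network trained on fixed-size crops applies unchanged to
#' any `h x w` input.
#'
#' @param image numeric `h x w` matrix (grayscale intensities; mean-centre
#'   with [preprocess()] to match the training-time input distribution).
#' @param params a [init_params()] object (or a trained one).
#' @return `h x w x 2` array of class probabilities in the order
#'   (background, cone); each pixel's probabilities sum to 1.
#' @export
forward <- function(image, params) {
  stopifnot(inherits(params, "network_params"))
  if (length(dim(image)) %in% c(0L, 1L)) stop("image must be 2D")
  d <- dim(image)
  if (d[1] < 8 || d[2] < 8) stop("image must be at least 8 x 8")
  .network_forward(image, params, keep_cache = FALSE)
}

#' Extract the cone-probability channel
#'
#' @param prob `h x w x 2` probability array from [forward()].
#' @return `h x w` matrix of per-pixel cone probabilities.
#' @export
cone_probability <- function(prob) {
  stopifnot(length(dim(prob)) == 3L, dim(prob)[3] == 2L)
  prob[, , 2, drop = TRUE]
}

# Backward pass: dP is (hw) x 2 gradient of the loss w.r.t. softmax output.
# Returns gradients in the same structure as params.
.network_backward <- function(dP, params, cache) {
  h <- cache$h; w <- cache$w; u <- params$meta$units
  P <- cache$P
  # softmax jacobian: dZ2 = P * (dP - rowSums(dP * P))
  dZ2 <- P * (dP - rowSums(dP * P))
  g_fc_out <- list(W = crossprod(cache$R1, dZ2), b = colSums(dZ2))
  dR1 <- dZ2 %*% t(params$fc_out$W)
  dZ1 <- dR1 * (cache$R1 > 0)
  g_fc_hidden <- list(W = crossprod(cache$Xf, dZ1), b = colSums(dZ1))
  dXf <- dZ1 %*% t(params$fc_hidden$W)
  df2 <- array(dXf, c(h, w, 4 * u))

  g_m2 <- vector("list", 4); da2 <- array(0, c(h, w, 1))
  for (d in 0:3) {
    bg <- .block_backward_train(df2[, , (d * u + 1):((d + 1) * u), drop = FALSE],
                                cache$m2[[d + 1]]$cache)
    g_m2[[d + 1]] <- bg
    da2 <- da2 + bg$dx
  }
  cv2 <- conv3x3_backward_cpp(da2, cache$a2, cache$f1,
                              as.numeric(params$conv2$W))
  g_conv2 <- list(W = array(cv2$dW, dim(params$conv2$W)),
                  b = as.numeric(cv2$db))
  df1 <- cv2$dX

  g_m1 <- vector("list", 4); da1 <- array(0, c(h, w, 1))
  for (d in 0:3) {
    bg <- .block_backward_train(df1[, , (d * u + 1):((d + 1) * u), drop = FALSE],
                                cache$m1[[d + 1]]$cache)
    g_m1[[d + 1]] <- bg
    da1 <- da1 + bg$dx
  }
  cv1 <- conv3x3_backward_cpp(da1, cache$a1, cache$image,
                              as.numeric(params$conv1$W))
  g_conv1 <- list(W = array(cv1$dW, dim(params$conv1$W)),
                  b = as.numeric(cv1$db))

  list(conv1 = g_conv1, mdlstm1 = g_m1, conv2 = g_conv2, mdlstm2 = g_m2,
       fc_hidden = g_fc_hidden, fc_out = g_fc_out)
}

#' Per-pixel multiplication count of the full network
#'
#' Sums, for one interior pixel, the multiplications of both 3x3
#' convolutions (`9 * k_in * k_out` each), the eight directional MDLSTM
#' blocks (via [count_block_multiplications()]), and the fully connected
#' head, then scales by the number of pixels.
#'
#' @param h,w image dimensions.
#' @param units MDLSTM units per block.
#' @param fc_hidden hidden width of the fully connected head.
#' @return total multiplication count (numeric, to avoid integer overflow).
#' @export
count_network_multiplications <- function(h, w, units = 32L,
                                          fc_hidden = 64L) {
  stopifnot(h >= 1, w >= 1)
  u <- units
  per_pixel <- 9 * 1 * 1 +                                  # conv 1 -> 1
    4 * count_block_multiplications(u, 1) +                 # first MDLSTM
    9 * (4 * u) * 1 +                                       # conv 4u -> 1
    4 * count_block_multiplications(u, 1) +                 # second MDLSTM
    4 * u * fc_hidden + fc_hidden * 2                       # fc head
  per_pixel * as.numeric(h) * as.numeric(w)
}
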