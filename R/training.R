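#' Mean-centre an image
#'
#' Subtracts the scalar mean of the image, leaving the variance untouched.
#' Applied to every network input (full images at prediction time, crops
#' during training).
#'
#' @param image numeric matrix with at least one pixel.
#' @return matrix of the same size with mean zero.
#' @export
preprocess <- function(image) {
  if (length(image) == 0) stop("cannot preprocess an empty image")
  if (!all(is.finite(image))) stop("non-finite values in image")
  image - mean(image)
}

# One-hot truth channels from a 0/1 mask: columns (background, cone).
.truth_onehot <- function(mask) {
  x <- as.numeric(mask)
  cbind(background = 1 - x, cone = x)
}

#' Generalised Dice Loss
#'
#' Soft-Dice objective over the two classes with inverse-squared
#' class-volume weights `w_x = 1 / (sum_i x_i)^2`, which rebalances the
#' heavily background-dominated segmentation problem:
#' `GDL = 1 - 2 * (sum_x w_x sum_i x_i p_i) / (sum_x w_x sum_i (x_i + p_i))`.
#' A class absent from the truth gets weight 0 (its term vanishes) so the
#' loss stays finite on background-only crops. For probabilistic
#' predictions the value lies in `[0, 1]`.
#'
#' @param pred `h x w x 2` probability array (background, cone), or an
#'   `n x 2` matrix of per-pixel probabilities.
#' @param truth 0/1 cone mask of matching size.
#' @return scalar loss.
#' @export
generalised_dice_loss <- function(pred, truth) {
  if (length(dim(pred)) == 3L) pred <- matrix(pred, ncol = 2)
  X <- .truth_onehot(truth)
  if (nrow(X) != nrow(pred)) stop("prediction and truth sizes differ")
  wx <- colSums(X)^-2
  wx[!is.finite(wx)] <- 0
  num <- sum(wx * colSums(X * pred))
  den <- sum(wx * colSums(X + pred))
  1 - 2 * num / den
}

# Gradient of the GDL w.r.t. the predicted probabilities (n x 2).
.gdl_gradient <- function(pred, truth) {
  if (length(dim(pred)) == 3L) pred <- matrix(pred, ncol = 2)
  X <- .truth_onehot(truth)
  wx <- colSums(X)^-2
  wx[!is.finite(wx)] <- 0
  num <- sum(wx * colSums(X * pred))
  den <- sum(wx * colSums(X + pred))
  dnum <- sweep(X, 2, wx, "*")
  dden <- matrix(wx, nrow(X), 2, byrow = TRUE)
  -2 * (dnum * den - num * dden) / den^2
}

#' Training configuration
#'
#' @param batch_size crops per minibatch.
#' @param crop_size side of the square training crops in pixels; must not
#'   exceed the smallest training-image dimension.
#' @param learning_rate,rms_decay,momentum RMSProp hyperparameters
#'   (momentum is kept at 0 and the decayed mean square uses
#'   `epsilon = 1e-10` inside the square root).
#' @param patience epochs without validation improvement before stopping.
#' @param epoch_size minibatches per epoch; `NULL` sizes an epoch so that
#'   about one full pass of training pixels is sampled:
#'   `ceiling(total pixels / (batch_size * crop_size^2))`.
#' @param max_epochs hard cap on epochs (a safety net around early
#'   stopping).
#' @param units MDLSTM units per block when `train()` initialises the
#'   network itself.
#' @param seed seed controlling initialisation and crop sampling.
#' @return list of class `training_config`.
#' @export
training_config <- function(batch_size = 8L, crop_size = 128L,
                            learning_rate = 0.001, rms_decay = 0.9,
                            momentum = 0, patience = 20L, epoch_size = NULL,
                            max_epochs = 500L, units = 32L, seed = 1L) {
  stopifnot(batch_size >= 1, crop_size >= 8, patience >= 1, max_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 crop_size = as.integer(crop_size),
                 learning_rate = learning_rate, rms_decay = rms_decay,
                 momentum = momentum, patience = as.integer(patience),
                 epoch_size = if (!is.null(epoch_size)) as.integer(epoch_size),
                 max_epochs = as.integer(max_epochs),
                 units = as.integer(units), seed = as.integer(seed),
                 rms_epsilon = 1e-10),
            class = "training_config")
}

#' Sample a minibatch of random training crops
#'
#' Draws `batch_size` crops: for each, an image is chosen uniformly, then a
#' `crop_size x crop_size` window at a uniform valid offset. The image crop
#' is mean-centred (the network input during training is the crop, so
#' centring operates per crop); the mask is cropped identically.
#'
#' @param samples list of samples, each with `image` and `mask` matrices.
#' @param crop_size square crop side.
#' @param batch_size number of crops.
#' @return list of `batch_size` lists with `image` and `mask`. Uses the
#'   current RNG stream; seed it for reproducible batches.
#' @export
sample_minibatch <- function(samples, crop_size, batch_size) {
  lapply(seq_len(batch_size), function(b) {
    si <- sample.int(length(samples), 1)
    s <- samples[[si]]
    d <- dim(s$image)
    if (d[1] < crop_size || d[2] < crop_size)
      stop("image ", si, " (", d[1], "x", d[2], ") is smaller than the ",
           crop_size, "x", crop_size, " crop")
    r0 <- sample.int(d[1] - crop_size + 1, 1)
    c0 <- sample.int(d[2] - crop_size + 1, 1)
    ri <- r0:(r0 + crop_size - 1); ci <- c0:(c0 + crop_size - 1)
    list(image = preprocess(s$image[ri, ci]), mask = s$mask[ri, ci])
  })
}

# ---- parameter-tree plumbing for the optimiser ------------------------------

.leaf_paths <- function(params) {
  out <- list()
  for (nm in c("conv1", "conv2", "fc_hidden", "fc_out"))
    for (f in c("W", "b")) out[[length(out) + 1]] <- c(nm, f)
  for (nm in c("mdlstm1", "mdlstm2"))
    for (d in 1:4)
      for (f in c("win", "rup", "rleft", "bias"))
        out[[length(out) + 1]] <- c(nm, d, f)
  out
}

.get_leaf <- function(tree, path) {
  for (p in path) tree <- if (grepl("^[0-9]+$", p)) tree[[as.integer(p)]] else tree[[p]]
  tree
}

.set_leaf <- function(tree, path, value) {
  if (length(path) == 1) { tree[[path]] <- value; return(tree) }
  key <- if (grepl("^[0-9]+$", path[1])) as.integer(path[1]) else path[1]
  tree[[key]] <- .set_leaf(tree[[key]], path[-1], value)
  tree
}

# Forward + GDL backward for one crop; returns loss and gradient tree.
.crop_loss_grad <- function(crop, params) {
  fw <- .network_forward(crop$image, params, keep_cache = TRUE)
  P <- matrix(fw$prob, ncol = 2)
  loss <- generalised_dice_loss(P, crop$mask)
  dP <- .gdl_gradient(P, crop$mask)
  list(loss = loss, grads = .network_backward(dP, params, fw$cache))
}

.accumulate_grads <- function(acc, g, paths, scale) {
  for (i in seq_along(paths)) {
    pth <- as.character(paths[[i]])
    acc[[i]] <- acc[[i]] + scale * as.numeric(.get_leaf(g, pth))
  }
  acc
}

#' Train the segmentation network with GDL and RMSProp
#'
#' Minimises the batch-mean Generalised Dice Loss over random crops using
#' RMSProp (learning rate 0.001, decay 0.9, momentum 0 by default). After
#' every epoch the mean GDL over the full validation images is computed;
#' training stops once that criterion has not improved for
#' `config$patience` epochs (or at `config$max_epochs`), and the parameters
#' of the best validation epoch are returned.
#'
#' @param train_set,val_set lists of samples with `image` and `mask`
#'   entries (e.g. from [generate_dataset()]).
#' @param config a [training_config()].
#' @param params optional starting [init_params()]; when `NULL` a network
#'   with `config$units` units is initialised from `config$seed`.
#' @param verbose print per-epoch progress?
#' @return list with `params` (best epoch) and `history` (data frame of
#'   epoch, train_loss, val_loss, val_pixel_dice, plus `best_epoch` and
#'   `stopped_epoch` attributes).
#' @export
train <- function(train_set, val_set, config = training_config(),
                  params = NULL, verbose = FALSE) {
  stopifnot(length(train_set) >= 1, length(val_set) >= 1)
  if (is.null(params)) params <- init_params(config$seed, config$units)
  set.seed(config$seed + 1L)

  n_px <- sum(vapply(train_set, function(s) prod(dim(s$image)), numeric(1)))
  epoch_size <- config$epoch_size
  if (is.null(epoch_size))
    epoch_size <- max(1L, ceiling(n_px / (config$batch_size *
                                            config$crop_size^2)))

  paths <- .leaf_paths(params)
  ms <- lapply(paths, function(p) .get_leaf(params, as.character(p)) * 0)

  val_metrics <- function(p) {
    losses <- dices <- numeric(length(val_set))
    for (i in seq_along(val_set)) {
      pr <- .network_forward(preprocess(val_set[[i]]$image), p)
      losses[i] <- generalised_dice_loss(pr, val_set[[i]]$mask)
      pc <- as.numeric(pr[, , 2]); m <- as.numeric(val_set[[i]]$mask)
      dices[i] <- 2 * sum(pc * m) / (sum(pc) + sum(m))
    }
    c(loss = mean(losses), dice = mean(dices))
  }

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_pixel_dice = numeric())
  best <- Inf; best_epoch <- 0L; best_params <- params
  for (epoch in seq_len(config$max_epochs)) {
    ep_loss <- 0
    for (step in seq_len(epoch_size)) {
      batch <- sample_minibatch(train_set, config$crop_size,
                                config$batch_size)
      acc <- lapply(ms, function(x) x * 0)
      bl <- 0
      for (crop in batch) {
        lg <- .crop_loss_grad(crop, params)
        bl <- bl + lg$loss / length(batch)
        acc <- .accumulate_grads(acc, lg$grads, paths, 1 / length(batch))
      }
      if (!is.finite(bl))
        stop("training diverged: non-finite loss at epoch ", epoch,
             ", step ", step)
      for (i in seq_along(paths)) {
        pth <- as.character(paths[[i]])
        ms[[i]] <- config$rms_decay * ms[[i]] + (1 - config$rms_decay) * acc[[i]]^2
        step_arr <- config$learning_rate * acc[[i]] /
          sqrt(ms[[i]] + config$rms_epsilon)
        params <- .set_leaf(params, pth, .get_leaf(params, pth) - step_arr)
      }
      ep_loss <- ep_loss + bl / epoch_size
    }
    vm <- val_metrics(params)
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = ep_loss,
                                val_loss = vm["loss"],
                                val_pixel_dice = vm["dice"]))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  pix-dice %.4f",
                      epoch, ep_loss, vm["loss"], vm["dice"]))
    if (vm["loss"] < best) {
      best <- vm["loss"]; best_epoch <- epoch; best_params <- params
    }
    if (epoch - best_epoch >= config$patience) break
  }
  rownames(history) <- NULL
  attr(history, "best_epoch") <- best_epoch
  attr(history, "stopped_epoch") <- nrow(history)
  list(params = best_params, history = history)
}
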