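test_that("preprocess centres the mean and preserves the variance", {
  expect_equal(preprocess(matrix(7, 4, 4)), matrix(0, 4, 4))
  expect_equal(preprocess(matrix(c(0, 2), 1, 2)), matrix(c(-1, 1), 1, 2))
  set.seed(1)
  img <- matrix(rnorm(100, 5, 3), 10, 10)
  out <- preprocess(img)
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(sd(out), sd(img))
  expect_error(preprocess(matrix(numeric(0), 0, 0)), "empty")
})

test_that("GDL attains its closed-form values", {
  truth <- matrix(c(1, 0, 0, 0), 2, 2)
  onehot <- cbind(1 - as.numeric(truth), as.numeric(truth))
  expect_equal(generalised_dice_loss(onehot, truth), 0)
  expect_equal(generalised_dice_loss(1 - onehot, truth), 1)
  # uniform 0.5 prediction on a 2x2 with one cone pixel:
  # w_c = 1, w_b = 1/9; N = 1.5/9 + 0.5; D = 5/9 + 3  =>  1 - 2N/D = 0.625
  expect_equal(generalised_dice_loss(matrix(0.5, 4, 2), truth), 0.625)
})

test_that("GDL is a proper [0,1] loss that improves toward the truth", {
  set.seed(31)
  for (rep in 1:20) {
    truth <- matrix(rbinom(64, 1, runif(1, 0.05, 0.5)), 8, 8)
    if (sum(truth) == 0) truth[1] <- 1
    p <- runif(64)
    pred <- cbind(1 - p, p)
    l <- generalised_dice_loss(pred, truth)
    expect_gte(l, 0); expect_lte(l, 1)
    # move predictions along the straight line toward the one-hot truth
    onehot <- cbind(1 - as.numeric(truth), as.numeric(truth))
    lambdas <- seq(0, 1, by = 0.25)
    ls <- vapply(lambdas, function(lam)
      generalised_dice_loss((1 - lam) * pred + lam * onehot, truth),
      numeric(1))
    expect_true(all(diff(ls) < 1e-12))
  }
})

test_that("GDL stays finite when a class is absent from the truth", {
  truth <- matrix(0, 4, 4)  # background-only crop
  p <- matrix(runif(16), 16, 1)
  l <- generalised_dice_loss(cbind(1 - p, p), truth)
  expect_true(is.finite(l))
  # and the perfect background prediction still scores 0
  expect_equal(generalised_dice_loss(cbind(rep(1, 16), rep(0, 16)), truth),
               0)
})

test_that("the analytic GDL gradient matches finite differences", {
  set.seed(13)
  truth <- matrix(rbinom(36, 1, 0.2), 6, 6)
  truth[1] <- 1
  p <- runif(36)
  pred <- cbind(1 - p, p)
  gr <- conefinder:::.gdl_gradient(pred, truth)
  eps <- 1e-7
  for (ii in sample(length(pred), 8)) {
    pp <- pred; pp[ii] <- pp[ii] + eps
    pm <- pred; pm[ii] <- pm[ii] - eps
    fd <- (generalised_dice_loss(pp, truth) -
             generalised_dice_loss(pm, truth)) / (2 * eps)
    expect_equal(gr[ii], fd, tolerance = 1e-5)
  }
})

test_that("minibatch sampling crops image and mask congruently", {
  set.seed(2)
  samples <- lapply(1:3, function(i) {
    img <- matrix(runif(40 * 50), 40, 50)
    list(image = img, mask = (img > 0.8) * 1L)
  })
  set.seed(5)
  batch <- sample_minibatch(samples, crop_size = 16, batch_size = 8)
  expect_length(batch, 8)
  for (b in batch) {
    expect_equal(dim(b$image), c(16, 16))
    expect_equal(dim(b$mask), c(16, 16))
    expect_equal(mean(b$image), 0, tolerance = 1e-12)  # per-crop centring
  }
  set.seed(5)
  batch2 <- sample_minibatch(samples, 16, 8)
  expect_identical(batch, batch2)  # fixed rng, identical batches
  # a crop the size of the image is the (centred) image itself
  one <- list(list(image = samples[[1]]$image[1:40, 1:40],
                   mask = samples[[1]]$mask[1:40, 1:40]))
  crop <- sample_minibatch(one, 40, 1)[[1]]
  expect_equal(crop$image, preprocess(one[[1]]$image))
  expect_error(sample_minibatch(samples, 64, 1), "smaller than")
})

test_that("short training runs are deterministic and honour patience", {
  set.seed(77)
  ds <- generate_dataset(3, 1, seed = 21, height = 32, width = 32)
  sets <- lapply(ds$samples, function(s) s[c("image", "mask")])
  cfg <- training_config(units = 2, crop_size = 32, batch_size = 2,
                         epoch_size = 1, patience = 3, max_epochs = 12,
                         seed = 4)
  f1 <- train(sets[1:2], sets[3], cfg)
  f2 <- train(sets[1:2], sets[3], cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  h <- f1$history
  best <- attr(h, "best_epoch"); stopped <- attr(h, "stopped_epoch")
  expect_equal(best, which.min(h$val_loss))
  # either early-stopped exactly `patience` epochs past the best epoch, or
  # ran into the max_epochs cap
  expect_true(stopped == best + cfg$patience || stopped == cfg$max_epochs)
})

test_that("training reduces the loss on an easy noiseless mosaic", {
  spec <- mosaic_spec(height = 48, width = 48, spacing = 16, jitter = 0,
                      noise_sigma = 0.01, background_sigma = 0.01,
                      seed = 31)
  s <- generate_sample(spec)
  set <- list(list(image = s$image, mask = s$mask))
  cfg <- training_config(units = 4, crop_size = 48, batch_size = 4,
                         epoch_size = 2, patience = 30, max_epochs = 18,
                         seed = 2)
  fit <- train(set, set, cfg)
  h <- fit$history
  expect_lt(min(h$val_loss), h$val_loss[1])
  expect_gt(h$val_pixel_dice[nrow(h)], h$val_pixel_dice[1])
})

test_that("GDL training resists class imbalance where plain CE collapses", {
  # a fixture with ~3% cone pixels; follow the steepest-descent direction
  # (normalised gradient steps, so the two losses get identical step sizes)
  # of GDL and of unweighted cross-entropy from the same initialisation
  spec <- mosaic_spec(height = 40, width = 40, spacing = 16, jitter = 0,
                      lobe_sigma = 1.2, lobe_offset = 3, occupancy = 1,
                      noise_sigma = 0.02, background_sigma = 0.02, seed = 9)
  cents <- generate_centroids(spec)
  img <- preprocess(render_image(cents, spec))
  mask <- make_mask(cents, 2, c(40, 40))
  expect_lt(mean(mask), 0.05)

  run <- function(lossgrad, steps = 80, lr = 0.3) {
    p <- init_params(seed = 10, units = 2)
    paths <- conefinder:::.leaf_paths(p)
    for (st in seq_len(steps)) {
      fw <- conefinder:::.network_forward(img, p, keep_cache = TRUE)
      P <- matrix(fw$prob, ncol = 2)
      g <- conefinder:::.network_backward(lossgrad(P), p, fw$cache)
      gn <- sqrt(sum(vapply(paths, function(pt)
        sum(as.numeric(conefinder:::.get_leaf(g, as.character(pt)))^2),
        numeric(1))))
      for (i in seq_along(paths)) {
        pt <- as.character(paths[[i]])
        p <- conefinder:::.set_leaf(p, pt, conefinder:::.get_leaf(p, pt) -
                                      lr * conefinder:::.get_leaf(g, pt) / gn)
      }
    }
    matrix(conefinder:::.network_forward(img, p), ncol = 2)
  }
  X <- cbind(1 - as.numeric(mask), as.numeric(mask))
  p_gdl <- run(function(P) conefinder:::.gdl_gradient(P, mask))
  p_ce <- run(function(P) -X / pmax(P, 1e-12) / nrow(X))
  cone_px <- as.numeric(mask) == 1

  # CE heads for the all-background optimum: cone pixels end up background
  # and indistinguishable from true background pixels
  expect_lt(mean(p_ce[cone_px, 2]), 0.1)
  expect_lt(abs(mean(p_ce[cone_px, 2]) - mean(p_ce[!cone_px, 2])), 0.05)
  # GDL keeps the minority class alive and discriminates it
  expect_gt(mean(p_gdl[cone_px, 2]), 0.5)
  expect_gt(mean(p_gdl[cone_px, 2]), mean(p_gdl[!cone_px, 2]) + 0.3)
})

test_that("training aborts with a diagnostic on divergence", {
  ds <- generate_dataset(2, 1, seed = 40, height = 32, width = 32)
  sets <- lapply(ds$samples, function(s) s[c("image", "mask")])
  p <- init_params(seed = 1, units = 2)
  p$fc_out$W[] <- NaN
  cfg <- training_config(units = 2, crop_size = 32, batch_size = 1,
                         epoch_size = 1, patience = 1, max_epochs = 2,
                         seed = 1)
  expect_error(train(sets[1], sets[2], cfg, params = p), "non-finite|finite")
})
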