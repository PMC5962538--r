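test_that("a noiseless full-occupancy lattice has uniform nearest-neighbour spacing", {
  spec <- mosaic_spec(height = 100, width = 100, spacing = 10, jitter = 0,
                      occupancy = 1, seed = 4)
  pts <- generate_centroids(spec)
  expect_gt(nrow(pts), 50)
  dm <- as.matrix(dist(pts)); diag(dm) <- Inf
  nn <- apply(dm, 1, min)
  # triangular lattice: all nearest neighbours at exactly the pitch
  expect_equal(unname(nn), rep(10, nrow(pts)), tolerance = 1e-9)
  # row pitch is spacing * sqrt(3)/2
  rows <- sort(unique(round(pts[, "row"], 9)))
  expect_equal(diff(rows), rep(10 * sqrt(3) / 2, length(rows) - 1),
               tolerance = 1e-9)
})

test_that("occupancy thins the lattice like binomial sampling", {
  full <- nrow(generate_centroids(
    mosaic_spec(height = 100, width = 100, spacing = 10, jitter = 0,
                occupancy = 1, seed = 1)))
  counts <- vapply(1:20, function(s) {
    nrow(generate_centroids(
      mosaic_spec(height = 100, width = 100, spacing = 10, jitter = 0,
                  occupancy = 0.3, seed = s)))
  }, numeric(1))
  expected <- 0.3 * full
  tol <- 4 * sqrt(full * 0.3 * 0.7 / 20)
  expect_lt(abs(mean(counts) - expected), tol)
})

test_that("generation is bit-deterministic in the seed", {
  spec <- mosaic_spec(spacing = 13, jitter = 0.15, occupancy = 0.8,
                      seed = 99)
  s1 <- generate_sample(spec); s2 <- generate_sample(spec)
  expect_identical(s1$centroids, s2$centroids)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  d1 <- generate_dataset(4, 0.5, seed = 3, height = 64, width = 64)
  d2 <- generate_dataset(4, 0.5, seed = 3, height = 64, width = 64)
  expect_identical(d1, d2)
})

test_that("an empty frame raises an empty-mosaic error", {
  expect_error(generate_centroids(
    mosaic_spec(height = 8, width = 8, spacing = 50, seed = 1)),
    "empty mosaic")
})

test_that("rendering without cones or noise is constant", {
  spec <- mosaic_spec(height = 32, width = 32, noise_sigma = 0,
                      background_sigma = 0, seed = 1)
  img <- render_image(matrix(numeric(0), 0, 2), spec)
  expect_equal(max(img) - min(img), 0)
})

test_that("a single dipole has antisymmetric column sums about its centre", {
  spec <- mosaic_spec(height = 41, width = 41, noise_sigma = 0,
                      background_sigma = 0, lobe_sigma = 2,
                      lobe_offset = 5, seed = 1)
  img <- render_image(cbind(row = 20, col = 20), spec, rescale = FALSE)
  cs <- colSums(img)
  # column 20 +/- delta sums are negatives of each other (0-based centre)
  for (delta in 1:15)
    expect_equal(cs[21 + delta], -cs[21 - delta], tolerance = 1e-10)
  expect_equal(cs[21], 0, tolerance = 1e-10)
})

test_that("the raw dipole field is additive over well-separated cones", {
  spec <- mosaic_spec(height = 64, width = 64, noise_sigma = 0,
                      background_sigma = 0, seed = 1)
  a <- render_image(cbind(row = 16, col = 16), spec, rescale = FALSE)
  b <- render_image(cbind(row = 48, col = 44), spec, rescale = FALSE)
  ab <- render_image(cbind(row = c(16, 48), col = c(16, 44)), spec,
                     rescale = FALSE)
  expect_equal(ab, a + b, tolerance = 1e-12)
})

test_that("mask disks contain exactly the pixels within the radius", {
  m <- make_mask(cbind(row = 5, col = 5), 3, c(11, 11))
  expect_equal(sum(m), 29)  # lattice points with distance <= 3
  m0 <- make_mask(cbind(row = 5, col = 5), 0.5, c(11, 11))
  expect_equal(which(m0 == 1), 5 * 11 + 6)  # only the centroid pixel
  m2 <- make_mask(cbind(row = c(5, 5), col = c(4, 6)), 3, c(11, 13))
  expect_lt(sum(m2), 2 * 29)  # overlapping disks union, not double count
  expect_error(make_mask(cbind(row = 20, col = 5), 3, c(11, 11)),
               "outside")
})

test_that("mask component centres recover the generating centroids", {
  spec <- mosaic_spec(height = 80, width = 80, spacing = 18, jitter = 0.05,
                      seed = 8)
  s <- generate_sample(spec)
  # flood-fill connected components of the noiseless mask (4-connectivity)
  lab <- matrix(0L, nrow(s$mask), ncol(s$mask)); nextl <- 0L
  for (start in which(s$mask == 1 & lab == 0)) {
    if (lab[start] != 0) next
    nextl <- nextl + 1L; queue <- start
    while (length(queue)) {
      px <- queue[[1]]; queue <- queue[-1]
      if (lab[px] != 0) next
      lab[px] <- nextl
      i <- (px - 1) %% nrow(lab) + 1; j <- (px - 1) %/% nrow(lab) + 1
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        if (nb[1] >= 1 && nb[1] <= nrow(lab) && nb[2] >= 1 &&
            nb[2] <= ncol(lab)) {
          q <- nb[1] + (nb[2] - 1) * nrow(lab)
          if (s$mask[q] == 1 && lab[q] == 0) queue <- c(queue, q)
        }
      }
    }
  }
  centres <- t(vapply(seq_len(nextl), function(l) {
    px <- which(lab == l)
    c(mean((px - 1) %% nrow(lab)), mean((px - 1) %/% nrow(lab)))
  }, numeric(2)))
  expect_equal(nrow(centres), nrow(s$centroids))
  # each component centre within 1 px of a generating centroid
  dm <- sqrt(outer(centres[, 1], s$centroids[, 1], "-")^2 +
               outer(centres[, 2], s$centroids[, 2], "-")^2)
  expect_lt(max(apply(dm, 1, min)), 1)
})

test_that("dataset regimes sit on the right sides of the density cut-off", {
  ds <- generate_dataset(24, 0.5, seed = 6, height = 96, width = 96)
  dens <- vapply(ds$samples, function(s)
    nrow(s$centroids) / prod(dim(s$image)), numeric(1))
  expect_equal(sum(ds$regime == "healthy"), 12)
  expect_true(all(dens[ds$regime == "healthy"] > 0.0011))
  expect_true(all(dens[ds$regime == "disease"] < 0.0011))
  expect_gt(mean(dens[ds$regime == "healthy"]), 0.0011)
  expect_lt(mean(dens[ds$regime == "disease"]), 0.0011)
  # images normalised to [0, 1]
  rngs <- range(vapply(ds$samples, function(s) range(s$image), numeric(2)))
  expect_gte(rngs[1], 0); expect_lte(rngs[2], 1)
})

test_that("spec validation rejects degenerate parameters", {
  expect_error(mosaic_spec(spacing = 1), "spacing")
  expect_error(mosaic_spec(occupancy = 0), "occupancy")
  expect_error(mosaic_spec(occupancy = 1.2), "occupancy")
  expect_error(mosaic_spec(lobe_sigma = -1), "lobe_sigma")
})
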