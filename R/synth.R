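#' Specification of a synthetic split-detection cone mosaic
#'
#' Describes one synthetic image: a quasi-hexagonal cone mosaic rendered in
#' split-detection appearance (each cone a horizontal dark/bright lobe pair)
#' over a smooth background with additive noise. Coordinates are (row, col),
#' 0-based, with pixel centres at integers.
#'
#' @param height,width image size in pixels.
#' @param spacing mean nearest-neighbour cone distance in pixels (`> 2`);
#'   the triangular lattice pitch.
#' @param jitter positional noise as a fraction of `spacing` (sd of the
#'   isotropic Gaussian perturbation applied to each lattice site).
#' @param occupancy fraction of lattice sites retained, in `(0, 1]`; low
#'   occupancy emulates patchy cone loss in diseased retina.
#' @param lobe_sigma Gaussian lobe scale in pixels.
#' @param lobe_offset separation of the dark and bright lobes in pixels.
#' @param contrast peak lobe amplitude (arbitrary intensity units).
#' @param noise_sigma sd of the additive white Gaussian noise.
#' @param background_sigma sd of the smooth background texture (white noise
#'   low-pass filtered at `4 * lobe_sigma`).
#' @param seed integer RNG seed; identical spec and seed reproduce the
#'   sample bit-exactly.
#' @return an object of class `mosaic_spec`.
#' @export
mosaic_spec <- function(height = 128, width = 128, spacing = 14,
                        jitter = 0.1, occupancy = 1, lobe_sigma = 2.1,
                        lobe_offset = 5.6, contrast = 0.9,
                        noise_sigma = 0.06, background_sigma = 0.1,
                        seed = 1L) {
  stopifnot(height >= 8, width >= 8, spacing > 2, jitter >= 0,
            occupancy > 0, occupancy <= 1, lobe_sigma > 0, lobe_offset > 0,
            contrast > 0, noise_sigma >= 0, background_sigma >= 0)
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0 || seed > 2^31 - 2e6 - 1)
    stop("seed must be an integer in [0, 2^31 - 2e6)")
  structure(as.list(environment()), class = "mosaic_spec")
}

#' Mask disk radius implied by a mosaic spec
#'
#' The ground-truth segmentation dilates each centroid to a disk whose
#' radius scales with the local cone spacing (0.35 of the spacing, at least
#' 2 px), so that disks cover most of each cone while leaving cone borders
#' visible.
#'
#' @param spec a [mosaic_spec()].
#' @return disk radius in pixels.
#' @export
disk_radius <- function(spec) max(2, 0.35 * spec$spacing)

#' Generate ground-truth cone centroids for a mosaic spec
#'
#' Places points on a triangular (hexagonal-packing) lattice of pitch
#' `spacing` (row pitch `spacing * sqrt(3)/2`, alternate rows offset by half
#' a pitch), perturbs each by isotropic Gaussian noise of sd
#' `jitter * spacing`, retains each independently with probability
#' `occupancy`, and removes points within [disk_radius()] of the image
#' border so every ground-truth disk fits inside the frame.
#'
#' @param spec a [mosaic_spec()].
#' @return numeric matrix with columns `row`, `col` (0-based, sub-pixel).
#' @export
generate_centroids <- function(spec) {
  stopifnot(inherits(spec, "mosaic_spec"))
  set.seed(spec$seed)
  s <- spec$spacing
  rp <- s * sqrt(3) / 2
  rows <- seq(0, spec$height - 1, by = rp)
  pts <- do.call(rbind, lapply(seq_along(rows), function(ri) {
    off <- if (ri %% 2 == 0) s / 2 else 0
    cols <- seq(off, spec$width - 1, by = s)
    if (!length(cols)) return(NULL)
    cbind(row = rows[ri], col = cols)
  }))
  m <- disk_radius(spec)
  usable <- !is.null(pts) &&
    any(pts[, 1] >= m & pts[, 1] <= spec$height - 1 - m &
          pts[, 2] >= m & pts[, 2] <= spec$width - 1 - m)
  if (!usable) stop("empty mosaic: no lattice sites inside the frame")
  pts[, 1] <- pts[, 1] + stats::rnorm(nrow(pts), 0, spec$jitter * s)
  pts[, 2] <- pts[, 2] + stats::rnorm(nrow(pts), 0, spec$jitter * s)
  keep <- stats::runif(nrow(pts)) <= spec$occupancy
  pts <- pts[keep, , drop = FALSE]
  m <- disk_radius(spec)
  inside <- pts[, 1] >= m & pts[, 1] <= spec$height - 1 - m &
    pts[, 2] >= m & pts[, 2] <= spec$width - 1 - m
  pts <- pts[inside, , drop = FALSE]
  colnames(pts) <- c("row", "col")
  pts
}

#' Render a split-detection image of a cone mosaic
#'
#' Each cone is drawn as a horizontal dipole: a negative Gaussian lobe at
#' `(row, col - lobe_offset/2)` and a positive one at
#' `(row, col + lobe_offset/2)`, both of sd `lobe_sigma` and amplitude
#' `contrast` — the left-dark/right-bright shading produced by the
#' split-detection difference channel. Dipoles are summed onto a smooth
#' background texture (white noise low-pass filtered with a Gaussian of sd
#' `4 * lobe_sigma`, rescaled to sd `background_sigma`) plus white Gaussian
#' noise of sd `noise_sigma`. When `rescale` is `TRUE` the result is mapped
#' affinely onto `[0, 1]` (a constant image maps to all zeros).
#'
#' @param centroids matrix with columns `row`, `col` (0-based) inside the
#'   frame.
#' @param spec a [mosaic_spec()].
#' @param rescale rescale intensities to `[0, 1]`? Disable to obtain the
#'   raw additive field (which is linear in the centroid set).
#' @return numeric `height x width` matrix.
#' @export
render_image <- function(centroids, spec, rescale = TRUE) {
  stopifnot(inherits(spec, "mosaic_spec"))
  h <- spec$height; w <- spec$width
  centroids <- as_centroids(centroids)
  if (nrow(centroids) &&
      (any(centroids[, 1] < 0) || any(centroids[, 1] > h - 1) ||
       any(centroids[, 2] < 0) || any(centroids[, 2] > w - 1)))
    stop("centroids must lie inside the frame")
  img <- matrix(0, h, w)
  rad <- ceiling(4 * spec$lobe_sigma + spec$lobe_offset / 2)
  for (n in seq_len(nrow(centroids))) {
    r0 <- centroids[n, 1]; c0 <- centroids[n, 2]
    ri <- max(0, floor(r0 - rad)):min(h - 1, ceiling(r0 + rad))
    ci <- max(0, floor(c0 - rad)):min(w - 1, ceiling(c0 + rad))
    gr <- exp(-(ri - r0)^2 / (2 * spec$lobe_sigma^2))
    gneg <- exp(-(ci - (c0 - spec$lobe_offset / 2))^2 / (2 * spec$lobe_sigma^2))
    gpos <- exp(-(ci - (c0 + spec$lobe_offset / 2))^2 / (2 * spec$lobe_sigma^2))
    img[ri + 1, ci + 1] <- img[ri + 1, ci + 1] +
      spec$contrast * outer(gr, gpos - gneg)
  }
  set.seed(spec$seed + 1000003L)
  if (spec$background_sigma > 0) {
    bg <- gaussian_smooth(matrix(stats::rnorm(h * w), h, w),
                          4 * spec$lobe_sigma)
    bgsd <- stats::sd(as.numeric(bg))
    if (bgsd > 0) img <- img + bg * (spec$background_sigma / bgsd)
  }
  if (spec$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
  if (rescale) {
    rng <- range(img)
    img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  }
  img
}

#' Build a binary segmentation mask by dilating centroids to disks
#'
#' A pixel belongs to the cone class iff its Euclidean distance to some
#' centroid is at most `disk_radius` (pixel centres at integer 0-based
#' coordinates). Overlapping disks union rather than double count.
#'
#' @param centroids matrix with columns `row`, `col` (0-based), all inside
#'   `shape`.
#' @param disk_radius disk radius in pixels, `>= 0.5`.
#' @param shape integer vector `c(height, width)`.
#' @return `height x width` matrix of 0 (background) / 1 (cone).
#' @export
make_mask <- function(centroids, disk_radius, shape) {
  stopifnot(disk_radius >= 0.5, length(shape) == 2)
  h <- shape[1]; w <- shape[2]
  centroids <- as_centroids(centroids)
  if (nrow(centroids) &&
      (any(centroids[, 1] < 0) || any(centroids[, 1] > h - 1) ||
       any(centroids[, 2] < 0) || any(centroids[, 2] > w - 1)))
    stop("centroid outside mask shape")
  mask <- matrix(0L, h, w)
  rad <- ceiling(disk_radius)
  for (n in seq_len(nrow(centroids))) {
    r0 <- centroids[n, 1]; c0 <- centroids[n, 2]
    ri <- max(0, floor(r0 - rad)):min(h - 1, ceiling(r0 + rad))
    ci <- max(0, floor(c0 - rad)):min(w - 1, ceiling(c0 + rad))
    d2 <- outer((ri - r0)^2, (ci - c0)^2, "+")
    mask[ri + 1, ci + 1] <- pmax(mask[ri + 1, ci + 1],
                                 (d2 <= disk_radius^2) * 1L)
  }
  mask
}

#' Generate one complete synthetic sample
#'
#' @param spec a [mosaic_spec()].
#' @return list of class `synthetic_sample` with elements `image`
#'   (`h x w` matrix in `[0, 1]`), `centroids` (ground truth), `mask`
#'   (0/1 matrix), `disk_radius`, and `spec`.
#' @export
generate_sample <- function(spec) {
  cents <- generate_centroids(spec)
  structure(list(image = render_image(cents, spec),
                 centroids = cents,
                 mask = make_mask(cents, disk_radius(spec),
                                  c(spec$height, spec$width)),
                 disk_radius = disk_radius(spec),
                 spec = spec),
            class = "synthetic_sample")
}

# Per-regime spec parameter ranges. Healthy retina: dense, regular, high
# contrast. Diseased (Stargardt-like) retina: sparse (well below the 0.0011
# cones/px dense/sparse cut-off), irregular, low contrast, noisier.
.regime_ranges <- function() {
  list(
    healthy = list(spacing = c(12, 16), jitter = c(0.06, 0.12),
                   occupancy = c(0.9, 1), contrast = c(0.7, 1),
                   noise_sigma = c(0.04, 0.08),
                   background_sigma = c(0.06, 0.12)),
    disease = list(spacing = c(22, 30), jitter = c(0.15, 0.25),
                   occupancy = c(0.2, 0.38), contrast = c(0.4, 0.6),
                   noise_sigma = c(0.1, 0.15),
                   background_sigma = c(0.1, 0.18))
  )
}

#' Generate a reproducible synthetic dataset of both mosaic regimes
#'
#' Draws per-image mosaic specs from per-regime parameter ranges (see
#' Details) and renders each sample. Healthy-regime images are dense
#' (cones-per-pixel well above 0.0011), disease-regime images sparse (below
#' it), by construction of the spacing/occupancy ranges.
#'
#' @details Lobe geometry is tied to spacing: `lobe_sigma = 0.15 * spacing`
#' and `lobe_offset = 0.4 * spacing`, so cones shrink and spread with the
#' mosaic scale as they do with retinal eccentricity.
#'
#' @param n_images number of samples, `>= 1`.
#' @param healthy_fraction fraction of images drawn from the healthy-dense
#'   regime (the first `round(n * fraction)` samples; the rest are
#'   disease-sparse).
#' @param seed master seed; per-image seeds and spec draws derive from it.
#' @param height,width image size of every sample.
#' @param ranges per-regime parameter ranges as returned by the internal
#'   default; override individual entries to move the study conditions.
#' @return list with `samples` (list of [generate_sample()] results) and
#'   `regime` (character vector, "healthy"/"disease").
#' @export
generate_dataset <- function(n_images, healthy_fraction = 0.5, seed = 1L,
                             height = 128, width = 128, ranges = NULL) {
  stopifnot(n_images >= 1, healthy_fraction >= 0, healthy_fraction <= 1)
  if (is.null(ranges)) ranges <- .regime_ranges()
  set.seed(seed)
  n_h <- round(n_images * healthy_fraction)
  regime <- rep(c("healthy", "disease"), c(n_h, n_images - n_h))
  seeds <- sample.int(2^31 - 2e6 - 1, n_images)
  draw <- function(rg) stats::runif(1, rg[1], rg[2])
  samples <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    rg <- ranges[[regime[i]]]
    sp <- draw(rg$spacing)
    spec <- mosaic_spec(height = height, width = width, spacing = sp,
                        jitter = draw(rg$jitter),
                        occupancy = draw(rg$occupancy),
                        lobe_sigma = 0.15 * sp, lobe_offset = 0.4 * sp,
                        contrast = draw(rg$contrast),
                        noise_sigma = draw(rg$noise_sigma),
                        background_sigma = draw(rg$background_sigma),
                        seed = seeds[i])
    samples[[i]] <- generate_sample(spec)
  }
  list(samples = samples, regime = regime)
}

# Coerce centroid input (matrix / data.frame with row,col) to a 2-column
# numeric matrix. Zero-row input is legal.
as_centroids <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("row", "col")])
  if (is.null(x) || length(x) == 0) {
    x <- matrix(numeric(0), 0, 2)
  }
  if (!is.matrix(x) || ncol(x) != 2) stop("centroids must be an n x 2 matrix (row, col)")
  storage.mode(x) <- "double"
  colnames(x) <- c("row", "col")
  x
}

#' Separable Gaussian smoothing of a matrix
#'
#' Convolves with a normalised Gaussian kernel of the given standard
#' deviation, truncated at 3 sd, using zero padding outside the image.
#' Shared by the synthetic background texture and the centroid-recovery
#' smoothing step.
#'
#' @param m numeric matrix.
#' @param sd Gaussian standard deviation in pixels.
#' @return smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(m, sd) {
  stopifnot(is.matrix(m), sd > 0)
  r <- max(1L, ceiling(3 * sd))
  kern <- stats::dnorm(-r:r, 0, sd)
  kern <- kern / sum(kern)
  band <- function(n) {
    K <- matrix(0, n, n)
    for (o in -r:r) {
      idx <- seq_len(n)
      src <- idx + o
      ok <- src >= 1 & src <= n
      K[cbind(idx[ok], src[ok])] <- kern[o + r + 1]
    }
    K
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}
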