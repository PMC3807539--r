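# Synthetic cardiac-like phantoms: bright quasi-convex object on a darker
# background with additive Gaussian noise. The generators stand in for
# clinical CT/MR data and are bit-deterministic under a fixed seed; all
# shapes are star-convex about their centre, matching the radial
# one-solution-per-section premise of the polar multiswarm model.

#' Phantom specification
#'
#' The boundary is `r(theta) = r0(theta) * (1 + sum_k a_k cos(k theta + phi_k))`
#' with harmonics k = 2..5 and seeded coefficients whose absolute sum equals
#' `perturbation` (< 0.5 keeps the shape star-convex). `r0(theta)` is the
#' base radius of a disk or an ellipse.
#'
#' @param shape `"disk"`, `"ellipse"` or `"blob"` (disk with perturbation).
#' @param radius base radius in px (disk/blob).
#' @param axes c(a, b) semi-axes in px (ellipse).
#' @param perturbation radial perturbation amplitude as a fraction (< 0.5).
#' @param object_intensity,background_intensity values in \[0, 1\], distinct.
#' @param noise_sigma additive Gaussian noise sd (intensity units).
#' @param seed RNG seed for the shape harmonics and noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c("blob", "disk", "ellipse"), radius = 34,
                         axes = c(34, 26), perturbation = 0.12,
                         object_intensity = 0.8, background_intensity = 0.25,
                         noise_sigma = 0.05, seed = 1L) {
  shape <- match.arg(shape)
  if (perturbation < 0 || perturbation >= 0.5)
    stop("perturbation must lie in [0, 0.5) to keep the shape star-convex")
  if (object_intensity == background_intensity)
    stop("object and background intensities must differ")
  structure(list(shape = shape, radius = radius, axes = axes,
                 perturbation = perturbation,
                 object_intensity = object_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_radius_fn <- function(spec) {
  # seeded harmonic coefficients; returns r(theta)
  set.seed(spec$seed)
  k <- 2:5
  raw <- stats::runif(length(k), -1, 1)
  amp <- if (spec$perturbation > 0 && sum(abs(raw)) > 0)
    raw * spec$perturbation / sum(abs(raw)) else raw * 0
  phase <- stats::runif(length(k), 0, 2 * pi)
  function(theta) {
    r0 <- switch(spec$shape,
      disk = ,
      blob = rep(spec$radius, length(theta)),
      ellipse = {
        a <- spec$axes[1]; b <- spec$axes[2]
        (a * b) / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
      })
    pert <- rep(0, length(theta))
    if (spec$shape != "disk")
      for (i in seq_along(k)) pert <- pert + amp[i] * cos(k[i] * theta + phase[i])
    r0 * (1 + pert)
  }
}

#' Rasterize a star-convex phantom mask
#'
#' @param spec a [phantom_spec()].
#' @param frame c(height, width).
#' @param centre c(row, col); frame centre if `NULL`.
#' @return numeric 0/1 matrix with attribute `"polar"` holding the centre
#'   and the boundary radius function r(theta).
#' @export
make_shape_mask <- function(spec, frame, centre = NULL) {
  h <- frame[1]; w <- frame[2]
  if (is.null(centre)) centre <- c((h - 1) / 2, (w - 1) / 2)
  rfn <- phantom_radius_fn(spec)
  th <- seq(0, 2 * pi, length.out = 721L)
  if (max(rfn(th)) > min(centre[1], centre[2], h - 1 - centre[1],
                         w - 1 - centre[2]))
    stop("shape exceeds the frame")
  cols <- rep(0:(w - 1), each = h); rows <- rep.int(0:(h - 1), w)
  dy <- rows - centre[1]; dx <- cols - centre[2]
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  m <- matrix(as.numeric(r <= rfn(theta)), h, w)
  attr(m, "polar") <- list(centre = centre, radius_fn = rfn)
  m
}

#' Render a phantom image from a mask
#'
#' Object/background intensities plus seeded additive Gaussian noise,
#' clipped to \[0, 1\]; the unrendered mask is the ground truth.
#'
#' @param mask numeric 0/1 matrix (typically from [make_shape_mask()]).
#' @param spec a [phantom_spec()] (intensities, noise, seed).
#' @return list(image, truth).
#' @export
render_phantom <- function(mask, spec) {
  check_mask(mask)
  img <- ifelse(mask == 1, spec$object_intensity, spec$background_intensity)
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed + 1L)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
  }
  img <- matrix(pmin(pmax(img, 0), 1), nrow(mask), ncol(mask))
  truth <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  list(image = img, truth = truth)
}

#' Generate a training set of transformed shapes
#'
#' Applies n seeded similarity transforms (uniform in the given ranges) to
#' the base phantom mask, emulating a training set of expert-delineated
#' shapes; the planted parameters are returned for recovery tests.
#' Transforms whose result is empty or touches the frame border are
#' resampled (up to 100 attempts each).
#'
#' @param base_spec a [phantom_spec()] for the base shape.
#' @param n number of shapes (>= 2).
#' @param frame c(height, width).
#' @param t_range max |translation| per axis in px.
#' @param s_range c(low, high) scale range.
#' @param theta_range max |rotation| in radians.
#' @param seed RNG seed for the planted parameters.
#' @return list(shapes, planted) where `planted` is a list of
#'   [shape_params()].
#' @export
make_training_set <- function(base_spec, n = 8L, frame = c(128L, 128L),
                              t_range = 6, s_range = c(0.9, 1.12),
                              theta_range = 10 * pi / 180, seed = 1L) {
  if (n < 2) stop("need n >= 2 shapes")
  base <- make_shape_mask(base_spec, frame)
  set.seed(seed)
  shapes <- vector("list", n)
  planted <- vector("list", n)
  for (i in seq_len(n)) {
    for (attempt in 1:100) {
      p <- shape_params(a = stats::runif(1, -t_range, t_range),
                        b = stats::runif(1, -t_range, t_range),
                        s = stats::runif(1, s_range[1], s_range[2]),
                        theta = stats::runif(1, -theta_range, theta_range))
      m <- apply_transform(base, build_transform(p))
      in_frame <- sum(m) > 0 &&
        sum(m[1, ]) + sum(m[nrow(m), ]) + sum(m[, 1]) + sum(m[, ncol(m)]) == 0
      if (in_frame) break
      if (attempt == 100) stop("could not place shape ", i, " in frame")
    }
    shapes[[i]] <- m
    planted[[i]] <- p
  }
  list(shapes = shapes, planted = planted)
}
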