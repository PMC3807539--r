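# Similarity transforms: translation + isotropic scale + in-plane rotation,
# composed in the fixed order M(a,b) %*% H(s) %*% R(theta) and applied to
# homogeneous coordinates (x, y, 1) with x = col, y = row.

norm_angle <- function(theta) {
  t <- (theta + pi) %% (2 * pi) - pi
  ifelse(t == -pi, pi, t) # normalize to (-pi, pi]
}

#' Similarity transform parameters
#'
#' @param a x-translation (px, along columns).
#' @param b y-translation (px, along rows).
#' @param s isotropic scale factor, > 0.
#' @param theta rotation angle in radians, normalized to (-pi, pi].
#' @return a `shape_params` list.
#' @export
shape_params <- function(a = 0, b = 0, s = 1, theta = 0) {
  if (!is.finite(s) || s <= 0) stop("scale s must be positive")
  structure(list(a = unname(a), b = unname(b), s = unname(s),
                 theta = unname(norm_angle(theta))),
            class = "shape_params")
}

#' Build a similarity transform matrix
#'
#' Homogeneous 3x3 matrix equal to the ordered product of translation,
#' scaling and rotation: it maps (x, y) to
#' (s(x cos t - y sin t) + a, s(x sin t + y cos t) + b).
#'
#' @param params a [shape_params()] object (or list with a, b, s, theta).
#' @return a `similarity_transform` with fields `matrix` and `params`.
#' @export
build_transform <- function(params) {
  if (!inherits(params, "shape_params"))
    params <- do.call(shape_params, as.list(params)[c("a", "b", "s", "theta")])
  M <- matrix(c(1, 0, params$a, 0, 1, params$b, 0, 0, 1), 3, 3, byrow = TRUE)
  H <- diag(c(params$s, params$s, 1))
  R <- matrix(c(cos(params$theta), -sin(params$theta), 0,
                sin(params$theta), cos(params$theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  structure(list(matrix = M %*% H %*% R, params = params),
            class = "similarity_transform")
}

#' Extract (a, b, s, theta) from a similarity transform
#'
#' @param transform a `similarity_transform` or bare 3x3 matrix.
#' @return a [shape_params()] object.
#' @export
transform_params <- function(transform) {
  m <- if (inherits(transform, "similarity_transform")) transform$matrix
       else transform
  s <- sqrt(det(m[1:2, 1:2]))
  shape_params(a = m[1, 3], b = m[2, 3], s = s,
               theta = atan2(m[2, 1], m[1, 1]))
}

#' Compose two similarity transforms (t1 after t2)
#'
#' @param t1,t2 `similarity_transform` objects.
#' @return the `similarity_transform` of `t1$matrix %*% t2$matrix`.
#' @export
compose_transform <- function(t1, t2) {
  m <- t1$matrix %*% t2$matrix
  structure(list(matrix = m, params = transform_params(m)),
            class = "similarity_transform")
}

#' Invert a similarity transform
#'
#' @param transform a `similarity_transform`.
#' @return the inverse `similarity_transform`.
#' @export
invert_transform <- function(transform) {
  m <- solve(transform$matrix)
  structure(list(matrix = m, params = transform_params(m)),
            class = "similarity_transform")
}

#' Apply a similarity transform to a binary mask
#'
#' Resamples by inverse mapping with nearest-neighbour interpolation so the
#' output stays binary. The matrix acts on coordinates relative to the frame
#' centre (rotation and scaling pivot about the image centre); pixels mapping
#' outside the frame become background. Output frame equals the input frame.
#'
#' @param mask numeric 0/1 matrix.
#' @param transform a `similarity_transform` (or [shape_params()], converted).
#' @return transformed numeric 0/1 matrix.
#' @export
apply_transform <- function(mask, transform) {
  check_mask(mask)
  if (inherits(transform, "shape_params")) transform <- build_transform(transform)
  h <- nrow(mask); w <- ncol(mask)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  inv <- solve(transform$matrix)
  cols <- rep(0:(w - 1), each = h)
  rows <- rep.int(0:(h - 1), w)
  x <- cols - cx; y <- rows - cy
  xs <- inv[1, 1] * x + inv[1, 2] * y + inv[1, 3]
  ys <- inv[2, 1] * x + inv[2, 2] * y + inv[2, 3]
  sc <- round(xs + cx); sr <- round(ys + cy)
  ok <- sc >= 0 & sc < w & sr >= 0 & sr < h
  out <- numeric(h * w)
  out[ok] <- mask[cbind(sr[ok] + 1, sc[ok] + 1)]
  matrix(out, h, w)
}

#' Foreground centroid of a mask
#'
#' @param mask numeric 0/1 matrix, non-empty.
#' @return c(row, col), 0-based real coordinates.
#' @export
mask_centroid <- function(mask) {
  check_mask(mask, require_nonempty = TRUE)
  idx <- which(mask == 1, arr.ind = TRUE)
  c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1)
}
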