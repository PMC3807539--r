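# Chan-Vese region energy with shape prior. These energies score a
# configuration (level set vs image and template); contour evolution itself
# is performed by the polar multiswarm optimizer, not by gradient flow.

#' Energy weights for the shape-prior total energy
#'
#' @param w1,w2,w3 non-negative weights of the region, shape and image terms.
#' @param mu non-negative weight of the contour-length term.
#' @param nu non-negative weight of the region-area term.
#' @param epsilon positive Heaviside regularization width.
#' @return an `energy_weights` list.
#' @export
energy_weights <- function(w1 = 1, w2 = 1, w3 = 1, mu = 0.1, nu = 0,
                           epsilon = 1) {
  v <- c(w1, w2, w3, mu, nu)
  if (any(!is.finite(v)) || any(v < 0)) stop("weights must be non-negative")
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(w1 = w1, w2 = w2, w3 = w3, mu = mu, nu = nu,
                 epsilon = epsilon), class = "energy_weights")
}

#' Mean intensities of object and background regions
#'
#' Heaviside-weighted means: `c1 = sum(I H(phi)) / sum(H(phi))` and
#' `c2 = sum(I (1 - H(phi))) / sum(1 - H(phi))`.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param phi signed level-set field (positive inside).
#' @param epsilon Heaviside regularization width.
#' @return c(c1, c2).
#' @export
region_means <- function(image, phi, epsilon = 1) {
  check_image(image)
  H <- smoothed_heaviside(phi, epsilon)
  sH <- sum(H); sHc <- sum(1 - H)
  if (sH <= 1e-12 || sHc <= 1e-12) stop("empty region under Heaviside")
  c(c1 = sum(image * H) / sH, c2 = sum(image * (1 - H)) / sHc)
}

#' Region (piecewise-constant fidelity) energy
#'
#' Chan-Vese data term plus regularizers:
#' `sum((I-c1)^2 H) + sum((I-c2)^2 (1-H)) + mu sum(|grad H|) + nu sum(H)`,
#' gradients by central differences.
#'
#' @inheritParams region_means
#' @param mu,nu length and area weights.
#' @return non-negative scalar.
#' @export
region_energy <- function(image, phi, mu = 0.1, nu = 0, epsilon = 1) {
  cc <- region_means(image, phi, epsilon)
  H <- smoothed_heaviside(phi, epsilon)
  fid <- sum((image - cc[1])^2 * H) + sum((image - cc[2])^2 * (1 - H))
  g <- grad_central(H)
  fid + mu * sum(sqrt(g$gx^2 + g$gy^2)) + nu * sum(H)
}

#' Shape-prior energy
#'
#' Squared Heaviside mismatch between the evolving region and the
#' similarity-transformed template:
#' `sum((H(phi) - H(phi_T))^2)` where `phi_T` is the signed distance field of
#' the transformed template mask. Zero iff the regions coincide (in the
#' sharp-Heaviside limit) and monotone in the symmetric difference.
#'
#' @param phi signed level-set field.
#' @param template a `template_shape` (frame must match `phi`).
#' @param transform similarity transform positioning the template; identity
#'   if `NULL`.
#' @param epsilon Heaviside regularization width.
#' @return non-negative scalar.
#' @export
shape_energy <- function(phi, template, transform = NULL, epsilon = 1) {
  tm <- template$union
  if (!all(dim(tm) == dim(phi))) stop("template frame must match phi frame")
  if (!is.null(transform)) tm <- apply_transform(tm, transform)
  if (sum(tm) == 0) stop("transform maps template fully outside the frame")
  phi_t <- signed_distance(tm)
  sum((smoothed_heaviside(phi, epsilon) - smoothed_heaviside(phi_t, epsilon))^2)
}

#' Image-based (gradient difference) energy
#'
#' `sum((grad H(phi) - grad I)^2)` summed over both gradient components,
#' central differences.
#'
#' @inheritParams region_means
#' @return non-negative scalar.
#' @export
image_energy <- function(phi, image, epsilon = 1) {
  check_image(image)
  gH <- grad_central(smoothed_heaviside(phi, epsilon))
  gI <- grad_central(image)
  sum((gH$gx - gI$gx)^2) + sum((gH$gy - gI$gy)^2)
}

#' Total shape-prior energy and its breakdown
#'
#' `e_total = w1 e1 + w2 e2 + w3 e3` with the region, shape and image
#' energies above.
#'
#' @inheritParams region_means
#' @param template a `template_shape`.
#' @param transform template-positioning similarity transform (or `NULL`).
#' @param weights an [energy_weights()] object.
#' @return an `energy_breakdown`: e1, e2, e3, e_total, c1, c2.
#' @export
total_energy <- function(image, phi, template, transform = NULL,
                         weights = energy_weights()) {
  eps <- weights$epsilon
  cc <- region_means(image, phi, eps)
  e1 <- region_energy(image, phi, mu = weights$mu, nu = weights$nu,
                      epsilon = eps)
  e2 <- shape_energy(phi, template, transform, epsilon = eps)
  e3 <- image_energy(phi, image, epsilon = eps)
  structure(list(
    e1 = e1, e2 = e2, e3 = e3,
    e_total = weights$w1 * e1 + weights$w2 * e2 + weights$w3 * e3,
    c1 = unname(cc[1]), c2 = unname(cc[2])
  ), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("E_total = %.4g (E1 = %.4g, E2 = %.4g, E3 = %.4g; c1 = %.3f, c2 = %.3f)\n",
              x$e_total, x$e1, x$e2, x$e3, x$c1, x$c2))
  invisible(x)
}
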