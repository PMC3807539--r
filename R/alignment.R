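# Shape alignment: similarity-transform registration of a training set of
# binary shapes by gradient descent on the pairwise overlap energy, and
# construction of the maximum-boundary template from the aligned set.

pair_energy <- function(mi, mj) {
  den <- sum((mi + mj)^2)
  if (den == 0) stop("degenerate pair: empty union")
  sum((mi - mj)^2) / den
}

#' Pairwise overlap energy of a shape set
#'
#' Sum over ordered pairs (i, j), i != j, of
#' `sum((I_i - I_j)^2) / sum((I_i + I_j)^2)` with integrals taken as pixel
#' sums. Zero iff all shapes coincide; each fully disjoint ordered pair
#' contributes exactly 1.
#'
#' @param shapes list of >= 2 numeric 0/1 matrices of equal size.
#' @return non-negative scalar.
#' @export
alignment_energy <- function(shapes) {
  n <- length(shapes)
  if (n < 2) stop("need at least two shapes")
  dims <- vapply(shapes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shapes must share a frame size")
  for (s in shapes) check_mask(s, require_nonempty = TRUE)
  e <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    e <- e + 2 * pair_energy(shapes[[i]], shapes[[j]])
  e
}

# energy restricted to ordered pairs involving shape i
partial_energy <- function(mask_i, others) {
  2 * sum(vapply(others, function(m) pair_energy(mask_i, m), numeric(1)))
}

#' Align binary shapes by similarity transforms
#'
#' Minimizes the pairwise overlap energy over per-shape (a, b, s, theta) by
#' gradient descent with numerical central-difference gradients (probe steps
#' `probe`) and backtracking halving of the step length when a trial step
#' fails to decrease the energy. The first shape is anchored at the identity
#' to fix the global-transform gauge. Resampling is nearest-neighbour so the
#' shapes stay binary throughout.
#'
#' @param shapes list of >= 2 numeric 0/1 matrices of equal size.
#' @param probe central-difference probe steps for (a, b, s, theta):
#'   default 0.5 px, 0.5 px, 0.01, 0.5 degree.
#' @param probe_schedule coarse-to-fine multipliers applied to `probe`; each
#'   stage runs sweeps to convergence before the probes shrink. Coarse probes
#'   are needed because the energy of nearest-neighbour-resampled binary
#'   shapes is piecewise constant: a probe must move the boundary by at least
#'   a pixel to sense the gradient.
#' @param step0 initial step length in probe units for the line search.
#' @param max_iters maximum number of full sweeps over the shapes (per
#'   schedule stage).
#' @param tolerance stop a stage when a sweep improves the energy by less
#'   than this.
#' @param init_grid initialize each shape against the anchored first shape by
#'   matching centroids and areas and grid-searching the rotation (accepted
#'   only when it lowers the energy) before descent; `FALSE` starts all
#'   shapes at the identity.
#' @return an `alignment_result`: `params` (list of [shape_params()]),
#'   `aligned` (list of masks), `energy_trace` (energy after each accepted
#'   step, starting at the identity-initialization energy), `converged`,
#'   `iterations`.
#' @export
align_shapes <- function(shapes,
                         probe = c(0.5, 0.5, 0.01, 0.5 * pi / 180),
                         probe_schedule = c(4, 2, 1),
                         step0 = 4, max_iters = 100, tolerance = 1e-7,
                         init_grid = TRUE) {
  n <- length(shapes)
  if (n < 2) stop("need at least two shapes")
  params <- replicate(n, c(a = 0, b = 0, s = 1, theta = 0), simplify = FALSE)
  aligned <- shapes
  dims <- dim(shapes[[1]])
  ctr_xy <- c((dims[2] - 1) / 2, (dims[1] - 1) / 2) # frame centre as (x, y)
  # cache of unordered pair energies
  pe <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    pe[i, j] <- pe[j, i] <- pair_energy(aligned[[i]], aligned[[j]])
  total <- 2 * sum(pe[upper.tri(pe)])
  if (!is.finite(total)) stop("non-finite alignment energy")
  trace <- total

  transform_of <- function(p) build_transform(shape_params(p[1], p[2], max(p[3], 0.05), p[4]))
  e_partial <- function(i, p) {
    m <- apply_transform(shapes[[i]], transform_of(p))
    if (sum(m) == 0) return(Inf) # shape pushed out of frame
    partial_energy(m, aligned[-i])
  }

  # moment-based initialization against the anchored first shape: match
  # centroids and areas, then grid-search the rotation angle (the energy of
  # nearest-neighbour-resampled binary shapes is noisy and multimodal in
  # theta, so pure local descent from the identity can stall)
  if (init_grid) {
    cen1 <- mask_centroid(shapes[[1]])
    c1 <- c(cen1[2], cen1[1]) - ctr_xy # centre-relative (x, y)
    a1 <- sum(shapes[[1]])
    th_grid <- seq(0, 45 * pi / 180, by = 2.5 * pi / 180)
    th_grid <- c(0, as.vector(rbind(th_grid[-1], -th_grid[-1]))) # by |theta|
    for (i in seq_len(n)[-1]) {
      ceni <- mask_centroid(shapes[[i]])
      ci <- c(ceni[2], ceni[1]) - ctr_xy
      s0 <- sqrt(a1 / sum(shapes[[i]]))
      cand_param <- function(th) {
        # translation keeping the scaled/rotated centroid on shape 1's
        R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
        t_xy <- c1 - s0 * as.vector(R %*% ci)
        c(a = t_xy[1], b = t_xy[2], s = s0, theta = th)
      }
      e_anchor <- function(p) {
        m <- apply_transform(shapes[[i]], transform_of(p))
        if (sum(m) == 0) return(Inf)
        pair_energy(m, shapes[[1]])
      }
      es <- vapply(th_grid, function(th) e_anchor(cand_param(th)), numeric(1))
      cand <- cand_param(th_grid[which.min(es)])
      if (min(es) < pair_energy(aligned[[i]], shapes[[1]])) {
        params[[i]] <- cand
        aligned[[i]] <- apply_transform(shapes[[i]], transform_of(cand))
      }
    }
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      pe[i, j] <- pe[j, i] <- pair_energy(aligned[[i]], aligned[[j]])
    init_total <- 2 * sum(pe[upper.tri(pe)])
    if (init_total <= total) {
      if (init_total < total) trace <- c(trace, init_total)
      total <- init_total
    } else {
      # revert: initialization must never worsen the identity energy
      params <- replicate(n, c(a = 0, b = 0, s = 1, theta = 0),
                          simplify = FALSE)
      aligned <- shapes
      for (i in 1:(n - 1)) for (j in (i + 1):n)
        pe[i, j] <- pe[j, i] <- pair_energy(aligned[[i]], aligned[[j]])
    }
  }

  iters_total <- 0L
  converged <- FALSE
  for (mult in probe_schedule) {
    prb <- probe * mult
    iter <- 0L
    converged <- FALSE
    while (iter < max_iters) {
      iter <- iter + 1L
      sweep_start <- total
      for (i in seq_len(n)[-1]) {
        p <- params[[i]]
        e0 <- partial_energy(aligned[[i]], aligned[-i])
        g <- numeric(4)
        for (k in 1:4) {
          pp <- p; pp[k] <- pp[k] + prb[k]
          pm <- p; pm[k] <- pm[k] - prb[k]
          g[k] <- (e_partial(i, pp) - e_partial(i, pm)) / (2 * prb[k])
        }
        if (!all(is.finite(g)) || all(g == 0)) next
        d <- g * prb
        d <- d / max(abs(d)) # largest component moves one probe unit per alpha
        accepted <- FALSE
        # backtracking line search along -gradient, then +gradient (the
        # resampled binary energy is locally noisy, so the finite-difference
        # sign can be unreliable near a minimum)
        for (sgn in c(-1, 1)) {
          alpha <- step0
          while (alpha >= 0.25) {
            cand <- p + sgn * alpha * prb * d
            et <- e_partial(i, cand)
            if (is.finite(et) && et < e0 - 1e-12) {
              pt <- cand; accepted <- TRUE; break
            }
            alpha <- alpha / 2
          }
          if (accepted) break
        }
        if (!accepted) {
          # per-coordinate pattern fallback: single +/- probe moves
          best_e <- e0
          for (k in 1:4) for (sgn in c(-1, 1)) {
            cand <- p; cand[k] <- cand[k] + sgn * prb[k]
            et <- e_partial(i, cand)
            if (is.finite(et) && et < best_e - 1e-12) {
              best_e <- et; pt <- cand; accepted <- TRUE
            }
          }
        }
        if (!accepted) next
        params[[i]] <- pt
        aligned[[i]] <- apply_transform(shapes[[i]], transform_of(pt))
        for (j in seq_len(n)[-i])
          pe[i, j] <- pe[j, i] <- pair_energy(aligned[[i]], aligned[[j]])
        total <- 2 * sum(pe[upper.tri(pe)])
        if (!is.finite(total)) stop("non-finite alignment energy")
        trace <- c(trace, total)
      }
      if (sweep_start - total < tolerance) { converged <- TRUE; break }
    }
    iters_total <- iters_total + iter
  }

  structure(list(
    params = lapply(params, function(p) shape_params(p[1], p[2], p[3], p[4])),
    aligned = aligned,
    energy_trace = trace,
    converged = converged,
    iterations = iters_total
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("alignment of", length(x$aligned), "shapes:",
      "energy", signif(x$energy_trace[1], 4), "->",
      signif(x$energy_trace[length(x$energy_trace)], 4),
      sprintf("(%d sweeps%s)\n", x$iterations,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Build the maximum-boundary shape template
#'
#' Superposes (pixelwise maximum) a set of aligned binary shapes; the
#' template boundary is the inner edge of the union — the maximum shape
#' boundary — and the centroid is the union's foreground centroid, used as
#' the reference origin for template placement.
#'
#' @param aligned list of >= 1 numeric 0/1 matrices of equal size.
#' @return a `template_shape`: `union`, `boundary`, `centroid` (row, col).
#' @export
build_template <- function(aligned) {
  if (length(aligned) < 1) stop("need at least one aligned shape")
  u <- Reduce(pmax, aligned)
  if (sum(u) == 0) stop("all aligned shapes are empty")
  structure(list(
    union = u,
    boundary = edge_mask(u),
    centroid = mask_centroid(u)
  ), class = "template_shape")
}

#' @export
print.template_shape <- function(x, ...) {
  cat(sprintf("shape template: %dx%d frame, area %d px, centroid (%.1f, %.1f)\n",
              nrow(x$union), ncol(x$union), as.integer(sum(x$union)),
              x$centroid[1], x$centroid[2]))
  invisible(x)
}
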