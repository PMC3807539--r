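# Polar geometry and mutual-information template placement.

#' Polar grid of constrained sections
#'
#' K angular sections around an origin; section i covers
#' \[2 pi (i-1)/K, 2 pi i/K) with bisector angle 2 pi (i - 0.5)/K. Angles are
#' measured with x = col, y = row.
#'
#' @param origin c(row, col), 0-based real coordinates.
#' @param n_sections number of sections K (>= 3).
#' @return a `polar_grid` with fields `origin`, `n_sections`, `angles`
#'   (bisector angles).
#' @export
polar_grid <- function(origin, n_sections) {
  if (n_sections < 3) stop("need at least 3 sections")
  i <- seq_len(n_sections)
  structure(list(origin = c(row = unname(origin[1]), col = unname(origin[2])),
                 n_sections = as.integer(n_sections),
                 angles = 2 * pi * (i - 0.5) / n_sections),
            class = "polar_grid")
}

#' Template boundary radius per polar section
#'
#' Casts the bisector ray of each section from the template centroid and
#' returns the largest radius at which the ray is still on template
#' foreground. Sections whose ray misses the template are interpolated from
#' the nearest resolved neighbours (circularly), with a message.
#'
#' @param template a `template_shape`.
#' @param n_sections number of sections.
#' @param step ray sampling step in px.
#' @return numeric vector of K radii.
#' @export
template_radii <- function(template, n_sections, step = 0.25) {
  u <- template$union
  ctr <- template$centroid
  h <- nrow(u); w <- ncol(u)
  rmax <- sqrt(h^2 + w^2)
  angles <- polar_grid(ctr, n_sections)$angles
  radii <- rep(NA_real_, n_sections)
  ts <- seq(0, rmax, by = step)
  for (i in seq_len(n_sections)) {
    rr <- ctr[1] + ts * sin(angles[i])
    cc <- ctr[2] + ts * cos(angles[i])
    ok <- rr >= 0 & rr <= h - 1 & cc >= 0 & cc <= w - 1
    if (!any(ok)) next
    fg <- u[cbind(round(rr[ok]) + 1, round(cc[ok]) + 1)] == 1
    if (any(fg)) radii[i] <- ts[ok][max(which(fg))]
  }
  if (anyNA(radii)) {
    if (all(is.na(radii))) stop("no section ray hits the template")
    message("interpolating ", sum(is.na(radii)),
            " section radii from neighbours")
    n <- n_sections
    for (i in which(is.na(radii))) {
      lo <- hi <- NA_real_
      for (d in 1:(n - 1)) { # nearest resolved neighbour each way
        j <- ((i - 1 - d) %% n) + 1
        if (!is.na(radii[j])) { lo <- radii[j]; break }
      }
      for (d in 1:(n - 1)) {
        j <- ((i - 1 + d) %% n) + 1
        if (!is.na(radii[j])) { hi <- radii[j]; break }
      }
      radii[i] <- mean(c(lo, hi), na.rm = TRUE)
    }
  }
  radii
}

mi_from_joint <- function(joint) {
  n <- sum(joint)
  p <- joint / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

bin_index <- function(x, bins) pmin(floor(x * bins) + 1L, bins)

#' Mutual information of two grayscale images
#'
#' MI of the joint intensity histogram over `bins` equal-width bins on
#' \[0, 1\], in nats.
#'
#' @param a,b numeric matrices in \[0, 1\] of equal size.
#' @param bins number of histogram bins (>= 2).
#' @return non-negative scalar.
#' @export
mutual_information <- function(a, b, bins = 32L) {
  if (!all(dim(a) == dim(b))) stop("images must share a frame size")
  if (bins < 2) stop("bins must be >= 2")
  ia <- bin_index(a, bins); ib <- bin_index(b, bins)
  joint <- matrix(tabulate((ia - 1L) * bins + ib, nbins = bins * bins),
                  bins, bins, byrow = TRUE)
  mi_from_joint(joint)
}

# MI between the image and a two-level template placed with its cropped
# bounding box at top-left (r0, c0) (0-based). Computed from the image-bin
# histogram split into inside/outside-template counts; identical to
# mutual_information(image, placed template) since empty joint cells add 0.
placement_mi <- function(ibin, tab_all, tmpl_idx_r, tmpl_idx_c, r0, c0, bins) {
  h <- nrow(ibin)
  lin <- (c0 + tmpl_idx_c - 1L) * h + (r0 + tmpl_idx_r)
  tab_fg <- tabulate(ibin[lin], nbins = bins)
  joint <- cbind(tab_all - tab_fg, tab_fg)
  mi_from_joint(joint)
}

#' Place the template on an image by maximum mutual information
#'
#' Slides the template (rendered as a two-level image over its bounding box)
#' across the frame on a `stride`-spaced translation grid, scores each
#' placement by mutual information with the image, refines at stride 1 around
#' the best cell, and returns the template centroid under the winning
#' translation. Ties break to the smallest row, then smallest column.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param template a `template_shape`, smaller than the frame.
#' @param stride coarse search stride in px.
#' @param bins histogram bins for the MI.
#' @return c(row, col): the placed template centroid (the polar origin).
#' @export
locate_origin <- function(image, template, stride = 2L, bins = 32L) {
  check_image(image)
  u <- template$union
  idx <- which(u == 1, arr.ind = TRUE)
  rmin <- min(idx[, 1]); rmax <- max(idx[, 1])
  cmin <- min(idx[, 2]); cmax <- max(idx[, 2])
  bh <- rmax - rmin + 1L; bw <- cmax - cmin + 1L
  h <- nrow(image); w <- ncol(image)
  if (bh > h || bw > w) stop("template larger than the image frame")
  tmpl_idx_r <- idx[, 1] - rmin + 1L # 1-based within bbox
  tmpl_idx_c <- idx[, 2] - cmin + 1L
  cen_off <- template$centroid - c(rmin - 1L, cmin - 1L) # centroid rel. bbox
  ibin <- matrix(bin_index(image, bins), h, w)
  tab_all <- tabulate(ibin, nbins = bins)

  best <- c(-Inf, NA, NA)
  eval_grid <- function(r0s, c0s, best) {
    for (r0 in r0s) for (c0 in c0s) {
      mi <- placement_mi(ibin, tab_all, tmpl_idx_r, tmpl_idx_c, r0, c0, bins)
      if (mi > best[1] + 1e-12) best <- c(mi, r0, c0)
    }
    best
  }
  r0s <- seq(0L, h - bh, by = stride)
  c0s <- seq(0L, w - bw, by = stride)
  if (length(r0s) == 0 || length(c0s) == 0) stop("no valid template placement")
  best <- eval_grid(r0s, c0s, best)
  if (stride > 1L) {
    r0s <- max(0L, best[2] - stride + 1L):min(h - bh, best[2] + stride - 1L)
    c0s <- max(0L, best[3] - stride + 1L):min(w - bw, best[3] + stride - 1L)
    best <- eval_grid(r0s, c0s, best)
  }
  c(row = unname(best[2] + cen_off[1]), col = unname(best[3] + cen_off[2]))
}
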