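# ---- validation helpers ------------------------------------------------------

#' Validate a grayscale image
#'
#' Images are plain numeric matrices with intensities in \[0, 1\]; pixel
#' (row, col) uses 0-based coordinates with x = col and y = row throughout the
#' package.
#'
#' @param image numeric matrix.
#' @param min_dim minimum height/width accepted.
#' @return the image, invisibly.
#' @export
check_image <- function(image, min_dim = 2L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stop("image must be at least ", min_dim, "x", min_dim)
  if (any(!is.finite(image)))
    stop("image contains non-finite values")
  if (min(image) < 0 || max(image) > 1)
    stop("image intensities must lie in [0, 1]")
  invisible(image)
}

#' Validate a binary mask
#'
#' Masks are numeric matrices taking values in \{0, 1\} exactly.
#'
#' @param mask numeric matrix of 0/1.
#' @param require_nonempty error if no foreground pixel.
#' @return the mask, invisibly.
#' @export
check_mask <- function(mask, require_nonempty = FALSE) {
  if (!is.matrix(mask) || !is.numeric(mask))
    stop("mask must be a numeric matrix")
  if (!all(mask %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1")
  if (require_nonempty && sum(mask) == 0)
    stop("mask has no foreground pixel")
  invisible(mask)
}

# ---- file I/O ----------------------------------------------------------------

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  # read header tokens (width, height, maxval), skipping comments
  tok <- character(0)
  buf <- character(0)
  while (length(tok) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header: ", path)
    if (ch == "#") { # comment to end of line
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (nchar(paste(buf, collapse = "")) > 0) {
        tok <- c(tok, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else buf <- c(buf, ch)
  }
  w <- as.integer(tok[1]); h <- as.integer(tok[2]); maxval <- as.integer(tok[3])
  if (maxval > 255L) stop("only 8-bit PGM supported")
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n))
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated PGM data: ", path)
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(m, path, maxval = 255L) {
  v <- round(t(m) * maxval) # row-major order
  header <- sprintf("P2\n%d %d\n%d\n", ncol(m), nrow(m), maxval)
  body <- paste(apply(matrix(as.integer(v), ncol = ncol(m)), 2, paste,
                      collapse = " "), collapse = "\n")
  writeLines(paste0(header, body), path)
  invisible(path)
}

#' Read a grayscale image from PNG or PGM
#'
#' 8-bit content is normalized to \[0, 1\] on load.
#'
#' @param path file path ending in .png, .pgm (P2 or P5).
#' @return numeric matrix with values in \[0, 1\].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- a[, , 1L] # first channel of RGB(A)
      a
    },
    pgm = read_pgm(path),
    stop("unsupported image format: ", ext)
  )
  check_image(m)
  m
}

#' Write a grayscale image to PNG or PGM
#'
#' @param image numeric matrix in \[0, 1\].
#' @param path output path (.png or .pgm).
#' @return the path, invisibly.
#' @export
save_image <- function(image, path) {
  check_image(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    pgm = write_pgm(image, path),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Read a binary mask
#'
#' Files are expected to hold \{0, 255\} (or \{0, 1\} after normalization);
#' other content is thresholded at 0.5 with a warning.
#'
#' @param path file path (.png or .pgm).
#' @return numeric 0/1 matrix.
#' @export
load_mask <- function(path) {
  m <- load_image(path)
  if (!all(m %in% c(0, 1))) {
    warning("mask file is not binary; thresholding at 0.5: ", path)
    m <- (m > 0.5) * 1
  }
  check_mask(m)
  m
}

#' Write a binary mask as a \{0, 255\} image
#'
#' Round-trips bit-exactly with [load_mask()].
#'
#' @param mask numeric 0/1 matrix.
#' @param path output path (.png or .pgm).
#' @return the path, invisibly.
#' @export
save_mask <- function(mask, path) {
  check_mask(mask)
  save_image(mask, path)
}

# ---- edge extraction ---------------------------------------------------------

#' Inner boundary of a binary mask
#'
#' A foreground pixel is an edge pixel when at least one of its 4-neighbours
#' (8-neighbours with `connectivity = 8`) is background; pixels on the image
#' border count frame-exterior pixels as background.
#'
#' @param mask numeric 0/1 matrix.
#' @param connectivity 4 (default) or 8.
#' @return numeric 0/1 matrix marking edge pixels.
#' @export
edge_mask <- function(mask, connectivity = 4L) {
  check_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  ctr <- pad[2:(h + 1L), 2:(w + 1L)]
  up <- pad[1:h, 2:(w + 1L)]; dn <- pad[3:(h + 2L), 2:(w + 1L)]
  lf <- pad[2:(h + 1L), 1:w]; rt <- pad[2:(h + 1L), 3:(w + 2L)]
  bgn <- (up == 0) | (dn == 0) | (lf == 0) | (rt == 0)
  if (connectivity == 8L) {
    bgn <- bgn | (pad[1:h, 1:w] == 0) | (pad[1:h, 3:(w + 2L)] == 0) |
      (pad[3:(h + 2L), 1:w] == 0) | (pad[3:(h + 2L), 3:(w + 2L)] == 0)
  }
  (ctr == 1 & bgn) * 1
}

grad_central <- function(m) {
  # central differences with replicated borders; returns d/dx (col) and d/dy (row)
  h <- nrow(m); w <- ncol(m)
  xr <- m[, c(2:w, w)]; xl <- m[, c(1, 1:(w - 1))]
  yd <- m[c(2:h, h), ]; yu <- m[c(1, 1:(h - 1)), ]
  list(gx = (xr - xl) / 2, gy = (yd - yu) / 2)
}

#' Gradient-magnitude edge mask of an intensity image
#'
#' Marks pixels whose central-difference gradient magnitude exceeds
#' `threshold` times the maximum gradient magnitude. An optional Gaussian
#' pre-smoothing (`smooth_sigma` in pixels) suppresses noise-induced edges.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param threshold fraction of the maximum gradient magnitude, in (0, 1).
#' @param smooth_sigma Gaussian smoothing sigma in px; 0 disables.
#' @return numeric 0/1 edge mask (empty, with a warning, for constant images).
#' @export
gradient_edge_mask <- function(image, threshold = 0.3, smooth_sigma = 0) {
  check_image(image)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (smooth_sigma > 0)
    image <- EBImage::imageData(EBImage::gblur(image, sigma = smooth_sigma))
  g <- grad_central(image)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mx <- max(mag)
  if (mx == 0) {
    warning("constant image: empty edge mask")
    return(matrix(0, nrow(image), ncol(image)))
  }
  (mag > threshold * mx) * 1
}

# ---- distance fields ---------------------------------------------------------

#' Euclidean distance map of an edge set
#'
#' Exact Euclidean distance transform: 0 on edge pixels, elsewhere the
#' distance (in px) to the nearest edge pixel. This is the fitness surface of
#' the polar multiswarm optimizer.
#'
#' @param edges numeric 0/1 matrix with at least one edge pixel.
#' @return numeric matrix of non-negative distances.
#' @export
distance_map <- function(edges) {
  check_mask(edges)
  if (sum(edges) == 0) stop("no edges to anchor fitness")
  d <- EBImage::distmap(1 - edges, metric = "euclidean")
  m <- EBImage::imageData(d)
  dim(m) <- dim(edges)
  m
}

#' Signed distance field of a binary mask
#'
#' Positive inside the object, negative outside; |field| is the distance to
#' the object boundary, taken to run between foreground and background pixel
#' centres (so the innermost/outermost pixels sit at +/-0.5 px). Thresholding
#' the field at 0 recovers the mask.
#'
#' @param mask numeric 0/1 matrix, neither empty nor full-frame.
#' @return numeric matrix (signed distances).
#' @export
signed_distance <- function(mask) {
  check_mask(mask)
  n_fg <- sum(mask)
  if (n_fg == 0 || n_fg == length(mask)) stop("mask has no boundary")
  d_bg <- EBImage::imageData(EBImage::distmap(mask, metric = "euclidean"))
  d_fg <- EBImage::imageData(EBImage::distmap(1 - mask, metric = "euclidean"))
  dim(d_bg) <- dim(mask); dim(d_fg) <- dim(mask)
  # distmap(x) is distance to the nearest 0-pixel of x:
  #   d_bg = distance to background (positive on fg), d_fg = distance to fg.
  phi <- ifelse(mask == 1, d_bg - 0.5, -(d_fg - 0.5))
  phi
}

#' Regularized Heaviside function
#'
#' The C1 arctan regularization `0.5 * (1 + (2/pi) * atan(value / epsilon))`,
#' used by all region energies; monotone in `value`, equal to 0.5 at 0, and
#' satisfying H(x) + H(-x) = 1.
#'
#' @param value numeric (vector or matrix of signed level-set values).
#' @param epsilon positive smoothing width.
#' @return values in (0, 1), same shape as `value`.
#' @export
smoothed_heaviside <- function(value, epsilon = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a positive scalar")
  0.5 * (1 + (2 / pi) * atan(value / epsilon))
}

bilinear_at <- function(m, row, col) {
  # interpolate m (0-based real coords); NA outside the frame
  h <- nrow(m); w <- ncol(m)
  out <- rep(NA_real_, length(row))
  ok <- is.finite(row) & is.finite(col) &
    row >= 0 & row <= h - 1 & col >= 0 & col <= w - 1
  if (!any(ok)) return(out)
  r <- row[ok]; c <- col[ok]
  r0 <- pmin(floor(r), h - 2L); c0 <- pmin(floor(c), w - 2L)
  fr <- r - r0; fc <- c - c0
  i <- r0 + 1L; j <- c0 + 1L
  v <- (1 - fr) * (1 - fc) * m[cbind(i, j)] +
    (1 - fr) * fc * m[cbind(i, j + 1L)] +
    fr * (1 - fc) * m[cbind(i + 1L, j)] +
    fr * fc * m[cbind(i + 1L, j + 1L)]
  out[ok] <- v
  out
}
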