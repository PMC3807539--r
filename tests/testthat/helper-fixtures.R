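# Shared fixtures, all built in code.

# filled disk mask: radius r centred at (cy, cx) (0-based) in an h x w frame
disk_mask <- function(h, w, r, cy = (h - 1) / 2, cx = (w - 1) / 2) {
  cols <- rep(0:(w - 1), each = h)
  rows <- rep.int(0:(h - 1), w)
  matrix(as.numeric((rows - cy)^2 + (cols - cx)^2 <= r^2), h, w)
}

# random mask with expected foreground fraction p
random_mask <- function(h, w, p = 0.3) {
  matrix(as.numeric(stats::runif(h * w) < p), h, w)
}

random_image <- function(h, w) matrix(stats::runif(h * w), h, w)

# brute-force Euclidean distance transform of an edge set
brute_distance_map <- function(edges) {
  idx <- which(edges == 1, arr.ind = TRUE)
  h <- nrow(edges); w <- ncol(edges)
  out <- matrix(NA_real_, h, w)
  for (r in 1:h) for (c in 1:w)
    out[r, c] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - c)^2))
  out
}

# brute-force inner 4-boundary via per-pixel neighbour scan
brute_edge_mask <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  at <- function(r, c) if (r < 1 || r > h || c < 1 || c > w) 0 else mask[r, c]
  for (r in 1:h) for (c in 1:w)
    if (mask[r, c] == 1 &&
        (at(r - 1, c) == 0 || at(r + 1, c) == 0 ||
         at(r, c - 1) == 0 || at(r, c + 1) == 0))
      out[r, c] <- 1
  out
}

# masks with a prescribed intersection / union pixel count, in one row
counts_mask_pair <- function(n_inter, n_union, w = n_union + 4L) {
  a <- matrix(0, 3, w); b <- matrix(0, 3, w)
  a[2, seq_len(n_union)] <- 1             # A = the whole union
  b[2, seq_len(n_inter)] <- 1             # B = the intersection only
  list(a = a, b = b)
}

expect_mask_equal <- function(x, y) expect_identical(unname(x), unname(y))
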