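# Validation metrics comparing a reference segmentation A with an automatic
# segmentation B: Jaccard, Dice, Pearson correlation of the indicator
# fields, directed (optionally symmetric) Hausdorff distance over edge
# pixels, and the maximum cardinality similarity metric (MCSM).

check_pair <- function(a, b) {
  check_mask(a); check_mask(b)
  if (!all(dim(a) == dim(b))) stop("masks must share a frame size")
}

#' Jaccard index |A ∩ B| / |A ∪ B|
#'
#' @param a,b numeric 0/1 matrices of equal size, union non-empty.
#' @return scalar in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  check_pair(a, b)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) stop("undefined similarity: both masks empty")
  sum(a == 1 & b == 1) / uni
}

#' Dice coefficient 2|A ∩ B| / (|A| + |B|)
#'
#' Related to the Jaccard index by D = 2J / (1 + J).
#'
#' @inheritParams jaccard
#' @return scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_pair(a, b)
  tot <- sum(a) + sum(b)
  if (tot == 0) stop("undefined similarity: both masks empty")
  2 * sum(a == 1 & b == 1) / tot
}

#' Pearson correlation of two mask indicator fields
#'
#' Correlation of the flattened 0/1 fields over all pixels.
#'
#' @inheritParams jaccard
#' @return scalar in \[-1, 1\].
#' @export
mask_correlation <- function(a, b) {
  check_pair(a, b)
  if (stats::var(as.vector(a)) == 0 || stats::var(as.vector(b)) == 0)
    stop("constant mask: correlation undefined")
  stats::cor(as.vector(a), as.vector(b))
}

#' Hausdorff distance between mask boundaries
#'
#' Directed form (as printed in the field's tables):
#' `max over edge pixels a of A of min over edge pixels b of B of ||a - b||`,
#' computed on the inner 4-connected boundaries. `symmetric = TRUE` returns
#' the max of both directions.
#'
#' @inheritParams jaccard
#' @param symmetric use the symmetric (two-sided) variant.
#' @return non-negative scalar (px).
#' @export
hausdorff_distance <- function(a, b, symmetric = FALSE) {
  check_pair(a, b)
  ea <- edge_mask(a); eb <- edge_mask(b)
  if (sum(ea) == 0 || sum(eb) == 0) stop("empty edge set")
  h_ab <- max(distance_map(eb)[ea == 1])
  if (!symmetric) return(h_ab)
  max(h_ab, max(distance_map(ea)[eb == 1]))
}

#' Maximum cardinality similarity metric
#'
#' Edge-matching score
#' `R_n = (N / (N - TP)) * (TP / (TP + FN) - TP / N)` where TP counts
#' reference edge pixels with a result edge pixel within `match_tolerance`
#' px, FN the remaining reference edge pixels, and N the total pixel count.
#' Equals 1 for a perfect match and 0 when no edge pixel matches.
#'
#' @param reference_edges,result_edges numeric 0/1 edge masks of equal size;
#'   the reference edge set must be non-empty.
#' @param match_tolerance matching radius in px (0 = exact coincidence).
#' @return scalar.
#' @export
mcsm <- function(reference_edges, result_edges, match_tolerance = 0) {
  check_pair(reference_edges, result_edges)
  n_ref <- sum(reference_edges)
  if (n_ref == 0) stop("reference edge set is empty")
  if (match_tolerance <= 0 || sum(result_edges) == 0) {
    tp <- sum(reference_edges == 1 & result_edges == 1)
  } else {
    d <- distance_map(result_edges)
    tp <- sum(d[reference_edges == 1] <= match_tolerance)
  }
  fn <- n_ref - tp
  n <- length(reference_edges)
  if (tp == n) stop("degenerate MCSM: TP equals the pixel count")
  (n / (n - tp)) * (tp / (tp + fn) - tp / n)
}

#' Five-metric evaluation of a segmentation against a reference
#'
#' Computes Jaccard, Dice, correlation, Hausdorff distance and MCSM with a
#' single shared edge extraction.
#'
#' @param reference,result numeric 0/1 matrices of equal size.
#' @param hausdorff `"directed"` (default) or `"symmetric"`.
#' @param mcsm_tolerance edge-matching tolerance in px for the MCSM.
#' @return a `metric_report` list: jaccard, dice, correlation, hausdorff,
#'   mcsm.
#' @export
evaluate_masks <- function(reference, result,
                           hausdorff = c("directed", "symmetric"),
                           mcsm_tolerance = 0) {
  hausdorff <- match.arg(hausdorff)
  check_pair(reference, result)
  e_ref <- edge_mask(reference); e_res <- edge_mask(result)
  if (sum(e_ref) == 0 || sum(e_res) == 0) stop("empty edge set")
  d_res <- distance_map(e_res)
  h <- max(d_res[e_ref == 1])
  if (hausdorff == "symmetric") h <- max(h, max(distance_map(e_ref)[e_res == 1]))
  structure(list(
    jaccard = jaccard(reference, result),
    dice = dice(reference, result),
    correlation = mask_correlation(reference, result),
    hausdorff = h,
    mcsm = mcsm(e_ref, e_res, mcsm_tolerance)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("J = %.4f  D = %.4f  rho = %.4f  H = %.3f px  MCSM = %.4f\n",
              x$jaccard, x$dice, x$correlation, x$hausdorff, x$mcsm))
  invisible(x)
}
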