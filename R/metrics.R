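# delineation evaluation: binarization, skeletonization, tolerance point
# matching, Completeness/Correctness/Quality, PR break-even, rater agreement
#
# Skeletons are represented either as 0/1 matrices or as n x 2 integer
# matrices of (row, col) pixel coordinates (1-based); conversion helpers
# accept both forms.

#' Threshold a probability map
#'
#' Strictly-greater comparison, so ties at the threshold go to background.
#'
#' @param prob numeric matrix in `[0, 1]`
#' @param threshold scalar threshold (default 0.5)
#' @return 0/1 integer matrix
#' @export
binarize <- function(prob, threshold = 0.5) {
  (prob > threshold) + 0L
}

#' Topology-preserving skeletonization
#'
#' Thins a binary mask to a 1-px-wide skeleton by two-subiteration
#' morphological thinning (Zhang-Suen family). Connected components of the
#' input remain connected in the skeleton, which is what makes the Quality
#' metric sensitive to breaks in vessel continuity rather than to vessel
#' width.
#'
#' @param mask binary matrix
#' @return 0/1 integer matrix of the same size
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  cpp_thin(m)
}

#' Convert a binary skeleton mask to an n x 2 coordinate matrix
#' @param mask binary matrix
#' @return integer matrix of (row, col) coordinates
#' @export
skeleton_points <- function(mask) {
  which(mask > 0, arr.ind = TRUE)[, 1:2, drop = FALSE]
}

# two-column matrices are point lists; anything else is a mask
as_points <- function(x) {
  if (is.matrix(x) && ncol(x) == 2L) x else skeleton_points(x)
}

#' Tolerance point matching
#'
#' Returns the subset of `A` whose nearest point in `B` lies at Euclidean
#' distance strictly below `tau` pixels. The strict inequality means
#' `tau = 1` introduces no tolerance on the integer pixel grid, where
#' distinct points are at distance >= 1.
#'
#' @param A,B n x 2 coordinate matrices (or binary masks)
#' @param tau tolerance in pixels (>= 1)
#' @return the matched subset of `A` (n x 2 matrix)
#' @export
match_points <- function(A, B, tau) {
  stopifnot(tau >= 1)
  A <- as_points(A); B <- as_points(B)
  if (nrow(A) == 0L || nrow(B) == 0L)
    return(A[integer(0L), , drop = FALSE])
  A[cpp_match_points(A, B, tau), , drop = FALSE]
}

#' Completeness, Correctness and Quality of a delineation
#'
#' Tolerance-relaxed recall (Completeness), precision (Correctness) and
#' IoU (Quality) computed on skeleton point sets:
#' \deqn{Completeness = |\mu_{\hat Y}(Y,\tau)| / |Y|}
#' \deqn{Correctness = |\mu_{Y}(\hat Y,\tau)| / |\hat Y|}
#' \deqn{Quality = |\mu_{Y}(\hat Y,\tau)| / (|\hat Y| - |\mu_{\hat Y}(Y,\tau)| + |Y|)}
#' where \eqn{\mu_B(A,\tau)} keeps the points of A strictly closer than
#' \eqn{\tau} pixels to some point of B.
#'
#' Degenerate conventions: both skeletons empty gives (1, 1, 1); an empty
#' prediction against a nonempty ground truth — or the reverse — gives
#' (0, 0, 0) with `degenerate = TRUE`.
#'
#' @param pred predicted skeleton (mask or point matrix)
#' @param gt ground-truth centerline (mask or point matrix)
#' @param tau matching tolerance in pixels (default 2)
#' @return object of class `delineation_metrics`: list with `completeness`,
#'   `correctness`, `quality`, `tau`, the four underlying counts and a
#'   `degenerate` flag
#' @export
delineation_metrics <- function(pred, gt, tau = 2) {
  stopifnot(tau >= 1)
  P <- as_points(pred); G <- as_points(gt)
  nP <- nrow(P); nG <- nrow(G)
  mk <- function(comp, corr, qual, gm, pm, degen) {
    structure(list(completeness = comp, correctness = corr, quality = qual,
                   tau = tau, n_gt = nG, n_pred = nP, n_gt_matched = gm,
                   n_pred_matched = pm, degenerate = degen),
              class = "delineation_metrics")
  }
  if (nP == 0L && nG == 0L) return(mk(1, 1, 1, 0L, 0L, TRUE))
  if (nP == 0L || nG == 0L) return(mk(0, 0, 0, 0L, 0L, TRUE))
  gm <- nrow(match_points(G, P, tau))  # ground-truth points explained
  pm <- nrow(match_points(P, G, tau))  # predicted points that are correct
  mk(gm / nG, pm / nP, pm / (nP - gm + nG), gm, pm, FALSE)
}

#' @export
print.delineation_metrics <- function(x, ...) {
  cat(sprintf(
    "Delineation metrics (tau = %g px)\n  Completeness: %.4f\n  Correctness:  %.4f\n  Quality:      %.4f\n  |Y| = %d, |Yhat| = %d%s\n",
    x$tau, x$completeness, x$correctness, x$quality, x$n_gt, x$n_pred,
    if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Precision-recall break-even point
#'
#' Pixel-to-pixel comparison of a probability map against the ground-truth
#' centerline dilated by 1 pixel, swept over 255 uniform thresholds. The
#' break-even value is the common value of precision and recall where the
#' two curves cross (linearly interpolated between the bracketing
#' thresholds); at break-even it coincides with the F1/Dice score.
#'
#' @param prob probability map in `[0, 1]`
#' @param gt_centerline binary centerline mask (undilated)
#' @return list of class `pr_result` with `thresholds`, `precision`,
#'   `recall` and `breakeven`
#' @export
pr_breakeven <- function(prob, gt_centerline) {
  assert_same_shape(prob, gt_centerline)
  if (!any(gt_centerline > 0))
    stop("ground-truth centerline is empty; PR break-even undefined")
  target <- dilate_centerline(gt_centerline, radius = 1L) > 0
  np <- sum(target)
  thresholds <- seq_len(255L) / 256
  precision <- numeric(255L)
  recall <- numeric(255L)
  pv <- prob[target]
  nv <- prob[!target]
  for (i in seq_along(thresholds)) {
    t <- thresholds[i]
    tp <- sum(pv > t)
    fp <- sum(nv > t)
    precision[i] <- if (tp + fp == 0L) 1 else tp / (tp + fp)
    recall[i] <- tp / np
  }
  gap <- precision - recall
  i <- which.min(abs(gap))
  breakeven <- (precision[i] + recall[i]) / 2
  # refine by interpolating across the sign change, when one exists
  cross <- which(gap[-255L] * gap[-1L] < 0)
  if (length(cross) > 0L) {
    j <- cross[1L]
    w <- abs(gap[j]) / (abs(gap[j]) + abs(gap[j + 1L]))
    breakeven <- (1 - w) * (precision[j] + recall[j]) / 2 +
      w * (precision[j + 1L] + recall[j + 1L]) / 2
  }
  structure(list(thresholds = thresholds, precision = precision,
                 recall = recall, breakeven = breakeven),
            class = "pr_result")
}

#' Inter-rater agreement by the Quality metric
#'
#' Scores one annotator's skeleton against the other's at several matching
#' tolerances. Note the measure is asymmetric in its arguments.
#'
#' @param skel_a skeleton treated as the prediction
#' @param skel_b skeleton treated as the ground truth
#' @param taus tolerances in pixels
#' @return named numeric vector of Quality values, one per tolerance
#' @export
rater_agreement <- function(skel_a, skel_b, taus = c(1, 2, 3)) {
  vapply(taus, function(t) delineation_metrics(skel_a, skel_b, t)$quality,
         numeric(1L)) |> setNames(paste0("tau", taus))
}

#' Count 8-connected components of a binary mask
#' @param mask binary matrix
#' @return integer component count
#' @export
count_components <- function(mask) {
  cpp_label_count(matrix(as.integer(mask > 0), nrow(mask), ncol(mask)))
}
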