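# shared fixtures and independent oracles for the test suite

# a hand-built vessel tree: branches are vertex matrices (row, col, depth)
make_tree <- function(branches, image_size = 16L, depth_slices = 16L) {
  structure(list(branches = branches, image_size = image_size,
                 depth_slices = depth_slices),
            class = "vessel_tree")
}

make_branch <- function(pts, width = 2, contrast = 0.8) {
  list(pts = pts, width = width, contrast = contrast)
}

# straight polyline between two endpoints with ~unit-length steps
line_pts <- function(p0, p1, depth = 0) {
  n <- max(abs(p1 - p0)) + 1L
  cbind(seq(p0[1L], p1[1L], length.out = n),
        seq(p0[2L], p1[2L], length.out = n), depth)
}

empty_tree <- function(image_size = 16L) make_tree(list(), image_size)

# O(|A| |B|) reference for tolerance matching (strict inequality)
brute_match <- function(A, B, tau) {
  if (nrow(A) == 0L || nrow(B) == 0L) return(A[integer(0L), , drop = FALSE])
  keep <- vapply(seq_len(nrow(A)), function(i) {
    d2 <- (B[, 1L] - A[i, 1L])^2 + (B[, 2L] - A[i, 2L])^2
    any(d2 < tau^2)
  }, logical(1L))
  A[keep, , drop = FALSE]
}

# reference delineation metrics from the brute-force matcher
brute_metrics <- function(pred, gt, tau) {
  gm <- nrow(brute_match(gt, pred, tau))
  pm <- nrow(brute_match(pred, gt, tau))
  list(completeness = gm / nrow(gt), correctness = pm / nrow(pred),
       quality = pm / (nrow(pred) - gm + nrow(gt)))
}

random_points <- function(n, lim = 40L) {
  cbind(sample.int(lim, n, replace = TRUE), sample.int(lim, n, replace = TRUE))
}

# tiny configs used across network/training tests
tiny_net <- function(...) {
  net_config(base_filters = 2L, n_blocks = 3L, ...)
}

tiny_phantoms <- function(n, size = 32L, seed = 5L) {
  phantom_dataset(n, phantom_config(image_size = size), seed = seed)
}
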