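#' Pearson correlation over an ROI
#'
#' Pixel-level Pearson correlation of two co-registered channels restricted
#' to a region of interest — the colocalization measure computed inside a
#' granule. Invariant to affine positive rescaling of either channel.
#'
#' @param a,b Image planes or matrices of identical dimensions.
#' @param roi Logical matrix selecting the pixels to correlate (>= 16).
#' @return Scalar Pearson r, or `NA` (with a warning) when either channel
#'   has zero variance over the ROI.
#' @examples
#' a <- matrix(runif(32 * 32), 32)
#' pearson_roi(a, 2 * a + 5, matrix(TRUE, 32, 32)) # exactly 1
#' @export
pearson_roi <- function(a, b, roi) {
  a <- as_matrix(a); b <- as_matrix(b)
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(roi))) {
    abort("`a`, `b` and `roi` must share dimensions.")
  }
  if (sum(roi) < 16L) abort("ROI must contain at least 16 pixels.")
  av <- a[roi]; bv <- b[roi]
  if (sd(av) == 0 || sd(bv) == 0) {
    warn("Pearson r undefined: zero variance within ROI.")
    return(NA_real_)
  }
  cor(av, bv)
}

#' Costes block-randomization colocalization test
#'
#' Significance test for ROI colocalization: channel `a` is tiled into
#' square blocks of physical size `block_size_um` (the block should match
#' the PSF scale, 0.12 um here), the blocks are permuted uniformly at
#' random, and Pearson r against channel `b` is recomputed each round. The
#' p-value is the add-one permutation fraction
#' \eqn{p = (1 + \#\{r_{rand} \ge r_{obs}\}) / (N + 1)}, so the smallest
#' attainable p is \eqn{1/(N+1)}.
#'
#' Blocks are anchored at the ROI bounding-box origin; blocks with < 50%
#' ROI coverage are excluded from shuffling, and both the observed and the
#' randomized coefficients are computed over the ROI pixels belonging to
#' included blocks (so the observed statistic and its null are measured on
#' the same pixel set).
#'
#' @param a,b Image planes or matrices; `a` is the shuffled channel.
#' @param roi Logical ROI mask.
#' @param block_size_um Block edge, micrometres; converted to pixels via
#'   the plane's pixel size and rounded to the nearest >= 1 px.
#' @param n_rounds Number of randomization rounds.
#' @param seed Integer RNG seed.
#' @param pixel_size_um Override for bare-matrix input.
#' @return A `coloc_result`: `observed_r`, `randomized_r` (length
#'   `n_rounds`), `p_value`, `n_rounds`, `block_size_px`, `n_blocks`,
#'   `roi` (the pixel set actually used).
#' @examples
#' set.seed(1)
#' a <- matrix(runif(64 * 64), 64)
#' res <- costes_randomization(a, a, matrix(TRUE, 64, 64),
#'                             block_size_um = 0.12 * 8, n_rounds = 99,
#'                             seed = 2, pixel_size_um = 0.12)
#' res$p_value # minimal: 1/100
#' @export
costes_randomization <- function(a, b, roi, block_size_um = 0.12,
                                 n_rounds = 1000L, seed = 1L,
                                 pixel_size_um = NULL) {
  px <- pixel_size_um %||% pixel_size(a)
  a <- as_matrix(a); b <- as_matrix(b)
  if (!all(dim(a) == dim(b)) || !all(dim(a) == dim(roi))) {
    abort("`a`, `b` and `roi` must share dimensions.")
  }
  bs <- max(1L, as.integer(round(block_size_um / px)))
  w <- which(roi, arr.ind = TRUE)
  if (nrow(w) == 0L) abort("empty ROI.")
  r0 <- min(w[, 1]); c0 <- min(w[, 2])
  r1 <- max(w[, 1]); c1 <- max(w[, 2])
  if (bs > (r1 - r0 + 1L) || bs > (c1 - c0 + 1L)) {
    abort("block size exceeds the ROI bounding box.")
  }
  # block grid anchored at the bounding-box origin; full blocks only
  n_br <- (r1 - r0 + 1L) %/% bs
  n_bc <- (c1 - c0 + 1L) %/% bs
  offsets <- as.matrix(expand.grid(dr = 0:(bs - 1L), dc = 0:(bs - 1L)))
  blocks <- list()
  for (bi in seq_len(n_br)) {
    for (bj in seq_len(n_bc)) {
      rows <- r0 + (bi - 1L) * bs + offsets[, 1]
      cols <- c0 + (bj - 1L) * bs + offsets[, 2]
      idx <- cbind(rows, cols)
      cov <- mean(roi[idx])
      if (cov >= 0.5) blocks[[length(blocks) + 1L]] <- idx
    }
  }
  n_blocks <- length(blocks)
  if (n_blocks < 4L) abort("ROI spans fewer than 4 usable blocks.")
  # linear pixel indices, one column per block
  lin <- vapply(blocks, function(idx) (idx[, 2] - 1L) * nrow(a) + idx[, 1],
                integer(bs * bs))
  use <- roi[lin] # which within-block pixels are ROI pixels
  a_blocks <- matrix(a[lin], nrow = bs * bs)
  b_sel <- b[lin][use]
  a_sel_obs <- a[lin][use]
  if (sd(a_sel_obs) == 0 || sd(b_sel) == 0) {
    abort("zero variance within ROI; Costes test undefined.")
  }
  observed_r <- cor(a_sel_obs, b_sel)
  randomized_r <- local_seed(seed, {
    vapply(seq_len(n_rounds), function(i) {
      perm <- sample.int(n_blocks)
      cor(a_blocks[, perm][use], b_sel)
    }, numeric(1))
  })
  p <- (1 + sum(randomized_r >= observed_r)) / (n_rounds + 1)
  roi_used <- matrix(FALSE, nrow(a), ncol(a))
  roi_used[lin[use]] <- TRUE
  structure(
    list(observed_r = observed_r, randomized_r = randomized_r,
         p_value = p, n_rounds = as.integer(n_rounds),
         block_size_px = bs, n_blocks = n_blocks, roi = roi_used),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result> r = %.3f, p = %.4g (%d rounds, %d blocks of %d px)\n",
    x$observed_r, x$p_value, x$n_rounds, x$n_blocks, x$block_size_px
  ))
  invisible(x)
}

#' Tidy a Costes colocalization result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return `tidy()`: the randomized coefficients, one row per round.
#'   `glance()`: one-row summary with `observed_r`, `p_value`, `n_rounds`,
#'   `block_size_px`, `n_blocks`.
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(round = seq_len(x$n_rounds), randomized_r = x$randomized_r)
}

#' @rdname tidy.coloc_result
#' @export
glance.coloc_result <- function(x, ...) {
  tibble(observed_r = x$observed_r, p_value = x$p_value,
         n_rounds = x$n_rounds, block_size_px = x$block_size_px,
         n_blocks = x$n_blocks)
}
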