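# Binary skeletonization (Zhang-Suen thinning).
#
# Iteratively peels boundary pixels while preserving connectivity, leaving a
# one-pixel-wide medial skeleton. Vectorized over the whole image via shifted
# neighbour views; out-of-image neighbours count as background.

shift_mat <- function(m, dr, dc) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0L, ny, nx)
  rs <- seq_len(ny) + dr; cs <- seq_len(nx) + dc
  ok_r <- rs >= 1 & rs <= ny; ok_c <- cs >= 1 & cs <= nx
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning to a one-pixel-wide skeleton; used by
#' [compute_diameters()] to place the local-diameter samples on vessel
#' centerlines.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  img <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours P2..P9 clockwise from north
      p2 <- shift_mat(img, -1L, 0L);  p3 <- shift_mat(img, -1L, 1L)
      p4 <- shift_mat(img, 0L, 1L);   p5 <- shift_mat(img, 1L, 1L)
      p6 <- shift_mat(img, 1L, 0L);   p7 <- shift_mat(img, 1L, -1L)
      p8 <- shift_mat(img, 0L, -1L);  p9 <- shift_mat(img, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- img == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- img == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        img[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1L
}
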