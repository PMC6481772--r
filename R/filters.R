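# Separable Gaussian filtering with symmetric (mirror) edge padding.
# Used by the synthetic abundance generator (smooth random fields) and by
# the local-statistics windows of the SSIM map.

gaussian_kernel <- function(size, sigma) {
  stopifnot(size >= 1, size %% 2 == 1, sigma > 0)
  x <- seq(-(size - 1) / 2, (size - 1) / 2)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# mirror-pad a matrix by `p` on every side (edge row/col repeated mirrored)
.pad_symmetric <- function(m, p) {
  if (p == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(pmin(p:1, nr), 1:nr, nr - pmin(1:p, nr) + 1L)
  ci <- c(pmin(p:1, nc), 1:nc, nc - pmin(1:p, nc) + 1L)
  m[ri, ci, drop = FALSE]
}

# 2-D Gaussian filter, separable implementation; output same shape as input
gaussian_filter2d <- function(m, sigma, size = NULL) {
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  if (size > 2L * min(nrow(m), ncol(m)) + 1L)
    stop("filter window larger than image allows")
  k <- gaussian_kernel(size, sigma)
  p <- (size - 1L) %/% 2L
  mp <- .pad_symmetric(m, p)
  nr <- nrow(m); nc <- ncol(m)
  # filter along rows (dimension 1)
  tmp <- matrix(0, nr, ncol(mp))
  for (j in seq_len(size))
    tmp <- tmp + k[j] * mp[(j - 1L) + seq_len(nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in seq_len(size))
    out <- out + k[j] * tmp[, (j - 1L) + seq_len(nc), drop = FALSE]
  out
}
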