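## Low-level segmentation primitives shared by the pipeline and ROI modules.

#' Otsu's threshold
#'
#' Histogram-based threshold maximizing between-class variance. Returns a
#' cut value t such that classifying pixels as foreground when
#' \code{x > t} best separates the two intensity classes. For a constant
#' input the threshold equals that constant (no pixel is strictly above it).
#'
#' @param x numeric vector or matrix of intensities (finite).
#' @param nbins number of histogram bins (default 256).
#' @return A single numeric threshold on the intensity scale.
#' @examples
#' x <- c(rnorm(500, 10, 1), rnorm(500, 100, 1))
#' t <- otsuThreshold(x)   # falls between the two modes
#' @export
otsuThreshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("otsuThreshold: intensities must be finite")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  omega <- cumsum(w)                      # class-0 weight up to each cut
  mu <- cumsum(w * mids)                  # class-0 first moment
  muT <- mu[nbins]
  # between-class variance at every candidate cut (after bin k)
  denom <- omega * (1 - omega)
  sigma_b <- (muT * omega - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(sigma_b)
  # cut at the upper edge of bin k: foreground is strictly above it
  breaks[k + 1L]
}

# Two-threshold (3-class) Otsu: maximizes between-class variance over all
# cut pairs. Returns c(low, high); the class at or below `low` is the
# darkest (media) class. Constant input returns that constant twice.
.otsuThreshold2 <- function(x, nbins = 128L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (rng[1] == rng[2]) return(c(rng[1], rng[1]))
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  W <- c(0, cumsum(w)); M <- c(0, cumsum(w * mids))
  best <- -Inf; bestCut <- c(1L, 2L)
  for (c1 in 1:(nbins - 2L)) {
    c2 <- (c1 + 1L):(nbins - 1L)
    w0 <- W[c1 + 1L];            m0 <- M[c1 + 1L]
    w1 <- W[c2 + 1L] - w0;       m1 <- M[c2 + 1L] - m0
    w2 <- 1 - w0 - w1;           m2 <- M[nbins + 1L] - m0 - m1
    sb <- ifelse(w0 > 0, m0^2 / w0, 0) + ifelse(w1 > 0, m1^2 / w1, 0) +
      ifelse(w2 > 0, m2^2 / w2, 0)
    j <- which.max(sb)
    if (sb[j] > best) {
      best <- sb[j]
      bestCut <- c(c1, c2[j])
    }
  }
  c(breaks[bestCut[1] + 1L], breaks[bestCut[2] + 1L])
}

#' Label connected components of a binary mask
#'
#' Two-pass union-find labelling (compiled); labels are contiguous positive
#' integers assigned in scan order, with 0 for background. 8-connectivity by
#' default, matching standard image-analysis practice for blob detection.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param minSizePx components with fewer pixels are removed (relabelled to
#'   0) and the remaining labels compacted; default 0 keeps everything.
#' @return Integer label matrix, same shape as \code{mask}.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[1:2, 1:2] <- TRUE; m[4:5, 4:5] <- TRUE
#' labelComponents(m)
#' @export
labelComponents <- function(mask, connectivity = 8L, minSizePx = 0L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  lab <- .cc_label(mask, as.integer(connectivity))
  if (minSizePx > 0L && max(lab) > 0L) {
    sizes <- .cc_sizes(lab)
    keep <- which(sizes >= minSizePx)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    lab[] <- ifelse(lab > 0L, remap[lab], 0L)
    lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  }
  lab
}

# Summed-area table: S[i+1, j+1] = sum(mask[1:i, 1:j]); O(1) window sums.
.integralImage <- function(mask) {
  s <- apply(mask, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

# Sum of mask over half-open window [r0, r0+h) x [c0, c0+w), 0-based r0/c0.
.windowSum <- function(S, r0, c0, h, w) {
  S[r0 + h + 1L, c0 + w + 1L] - S[r0 + 1L, c0 + w + 1L] -
    S[r0 + h + 1L, c0 + 1L] + S[r0 + 1L, c0 + 1L]
}
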