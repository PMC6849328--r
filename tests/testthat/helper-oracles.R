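# Shared fixtures and independent oracles used across test files.

# Brute-force tiling oracle: enumerate every step-aligned offset whose
# window fits, by explicit looping (independent of tileFovs' arithmetic).
enumerateWindowsOracle <- function(h, w, window, step) {
  out <- list()
  r <- 0L
  while (r + window <= h) {
    c <- 0L
    while (c + window <= w) {
      out[[length(out) + 1L]] <- c(r, c)
      c <- c + step
    }
    r <- r + step
  }
  if (!length(out)) return(data.frame(row0 = integer(0), col0 = integer(0)))
  m <- do.call(rbind, out)
  data.frame(row0 = m[, 1], col0 = m[, 2])
}

# Two-level image: fraction `fg` of pixels at `high`, rest at `low`.
twoLevelImage <- function(n = 100, fg = 0.5, low = 10, high = 100) {
  px <- matrix(low, n, n)
  k <- round(fg * n * n)
  if (k > 0) px[seq_len(k)] <- high
  IntensityImage(px)
}

# Noiseless synthetic image at a small size; returns image + truth.
smallSynthetic <- function(seed = 1, noiseSd = 0, confluence = 0.9,
                           target = NA, dropletDensity = 0, size = 500,
                           nCells = NA) {
  generateSrsImage(imageGenParams(
    heightPx = size, widthPx = size, confluence = confluence,
    nCells = nCells, targetLipidFraction = target,
    dropletDensity = dropletDensity, noiseSd = noiseSd, seed = seed))
}

# Grubbs oracle: direct formula, written independently of grubbsTest().
grubbsOracle <- function(x, alpha = 0.05) {
  n <- length(x)
  G <- max(abs(x - mean(x))) / sd(x)
  tcrit <- qt(alpha / (2 * n), n - 2, lower.tail = FALSE)
  Gcrit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  list(G = G, crit = Gcrit, reject = G > Gcrit)
}
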