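# Independent oracles and small builders shared across tests.

nrmse <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

# Brute-force evaluation of the DFT of a slice at every pseudo-polar
# frequency, straight from the exponential sums (O(N^4); N <= 32).
brute_pp_sector <- function(x, sector = c("BH", "BV")) {
  sector <- match.arg(sector)
  if (sector == "BV") x <- t(x)
  N <- nrow(x)
  u <- seq_len(N) - 1 - N / 2
  ks <- seq(-N, N - 1)
  ls <- seq(-N / 2, N / 2)
  out <- matrix(0i, 2 * N, N + 1)
  for (li in seq_along(ls)) {
    s <- 2 * ls[li] / N
    w <- outer(u, u, function(a, b) a + s * b)
    for (ki in seq_along(ks)) {
      out[ki, li] <- sum(x * exp(-2i * pi * ks[ki] * w / (2 * N)))
    }
  }
  out
}

brute_pp <- function(x) {
  list(BH = brute_pp_sector(x, "BH"), BV = brute_pp_sector(x, "BV"))
}

# Nonnegative band-limited test slice: mixture of Gaussian blobs kept deep
# inside the inscribed disk so the wings are negligible at the disk edge.
gauss_blob_slice <- function(N, sigma = 3.4, n_blobs = 6, seed = 1,
                             centre_radius = N / 8) {
  set.seed(seed)
  cc <- seq_len(N) - 1 - N / 2
  x <- matrix(0, N, N)
  for (i in seq_len(n_blobs)) {
    repeat {
      ctr <- stats::runif(2, -1, 1) * centre_radius
      if (sum(ctr^2) <= centre_radius^2) break
    }
    amp <- stats::runif(1, 0.3, 1.2)
    x <- x + amp * exp(-(outer((cc - ctr[1])^2, (cc - ctr[2])^2, "+")) /
                         (2 * sigma^2))
  }
  x
}

# Hard-edged slice smoothed to a given band limit (has compact features).
blurred_feature_slice <- function(N, sigma = 1.5, seed = 2) {
  set.seed(seed)
  cc <- seq_len(N) - 1 - N / 2
  x <- matrix(0, N, N)
  x[(outer(cc^2, 1.4 * cc^2, "+")) < (0.4 * N)^2] <- 0.4
  for (i in 1:5) {
    ctr <- round(stats::runif(2, -0.25, 0.25) * N)
    x[(outer((cc - ctr[1])^2, (cc - ctr[2])^2, "+")) < (0.05 * N)^2] <- 1.4
  }
  f <- c(0:(N / 2), (-N / 2 + 1):(-1)) / N
  H <- exp(-2 * pi^2 * sigma^2 * outer(f^2, f^2, "+"))
  x <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / N^2
  pmax(x, 0)
}

# Measured-line spectra of a slice restricted to an angle set, as the EST
# machinery sees them (for error-metric and direct-inversion comparisons).
masked_spectrum <- function(slice, angles) {
  sp <- ppfft2(slice)
  N <- sp$grid_size_N
  m <- angles[angles$measured, ]
  keepBH <- rep(FALSE, N + 1); keepBV <- rep(FALSE, N + 1)
  for (i in seq_len(nrow(m))) {
    col <- m$slope[i] + N / 2 + 1
    if (m$sector[i] == "BH") {
      keepBH[col] <- TRUE
      if (m$slope[i] == -N / 2) keepBV[col] <- TRUE
    } else {
      keepBV[col] <- TRUE
      if (m$slope[i] == N / 2) keepBH[col] <- TRUE
    }
  }
  sp$BH[, !keepBH] <- 0
  sp$BV[, !keepBV] <- 0
  sp$measured <- list(BH = keepBH, BV = keepBV)
  sp
}

dice <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

dilate2 <- function(m) {
  out <- m
  n1 <- nrow(m); n2 <- ncol(m)
  out[-1, ] <- out[-1, ] | m[-n1, ]
  out[-n1, ] <- out[-n1, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -n2]
  out[, -n2] <- out[, -n2] | m[, -1]
  out
}
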