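# Independent oracles: deliberately naive implementations used to verify
# the FFT-based production code. They share no code with the package
# internals.

# Direct sliding-lag circular autocorrelation, mean-subtracted and
# normalized, returned with zero lag at (floor(n/2)+1, floor(n/2)+1).
oracle_acf <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x <- x - mean(x)
  raw <- matrix(0, n1, n2)  # FFT order: raw[dr+1, dc+1]
  for (dr in 0:(n1 - 1)) {
    ri <- ((seq_len(n1) - 1 + dr) %% n1) + 1
    for (dc in 0:(n2 - 1)) {
      ci <- ((seq_len(n2) - 1 + dc) %% n2) + 1
      raw[dr + 1, dc + 1] <- sum(x * x[ri, ci])
    }
  }
  raw <- raw / raw[1, 1]
  cen <- matrix(0, n1, n2)
  c1 <- floor(n1 / 2) + 1; c2 <- floor(n2 / 2) + 1
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    cen[i, j] <- raw[((i - c1) %% n1) + 1, ((j - c2) %% n2) + 1]
  }
  cen
}

# Direct-sum DFT power spectrum averaged over vertical frequencies, one
# value per positive horizontal frequency (DC excluded). Small images only.
oracle_hspectrum <- function(x, pixel_size_um, hann = FALSE) {
  n1 <- nrow(x); n2 <- ncol(x)
  x <- x - mean(x)
  if (hann) {
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(n2 - 1)) / (n2 - 1))
    x <- sweep(x, 2, w, "*")
  }
  kmax <- floor(n2 / 2)
  pw <- numeric(kmax)
  for (kx in 1:kmax) {
    tot <- 0
    for (ky in 0:(n1 - 1)) {
      ph <- -2 * pi * (outer(0:(n1 - 1) * ky / n1,
                             0:(n2 - 1) * kx / n2, "+"))
      tot <- tot + Mod(sum(x * exp(1i * ph)))^2
    }
    pw[kx] <- tot / n1
  }
  list(freq = (1:kmax) / (n2 * pixel_size_um), power = pw)
}

# Per-pixel distance binning radial profile about a (1-based) centre.
oracle_radial <- function(m, center, bin = 1, pixel_size_um = 1) {
  kmax <- floor(sqrt(max((c(1, nrow(m)) - center[1])^2) +
                     max((c(1, ncol(m)) - center[2])^2)) / bin) + 1
  sums <- numeric(kmax); cnts <- numeric(kmax)
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    k <- floor(sqrt((i - center[1])^2 + (j - center[2])^2) / bin) + 1
    sums[k] <- sums[k] + m[i, j]; cnts[k] <- cnts[k] + 1
  }
  keep <- cnts > 0
  list(axis = ((which(keep) - 1) + 0.5) * bin * pixel_size_um,
       values = (sums / cnts)[keep])
}

# Dense-interpolation 26%-of-range downward crossing of a radial profile
# (axis/values vectors); returns the diameter in the axis units.
oracle_fw_fraction <- function(axis, values, fraction = 0.26) {
  thr <- min(values) + fraction * (max(values) - min(values))
  g <- seq(axis[1], axis[length(axis)], length.out = 200000)
  v <- stats::approx(axis, values, xout = g)$y
  k <- which(v[-length(v)] >= thr & v[-1] < thr)[1]
  2 * g[k]
}

# Build an acf_map object around a given matrix of ACF values (for profile
# operations that take a map as input).
fake_acf_map <- function(values, pixel_size_um = 0.05) {
  structure(list(values = values, pixel_size_um = pixel_size_um,
                 center = c(floor(nrow(values) / 2) + 1,
                            floor(ncol(values) / 2) + 1)),
            class = "acf_map")
}

# 90-degree counter-clockwise rotation of a matrix (exact, no resampling).
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Render top-hat disks of radius r_px at the given (row, col) 1-based
# centres onto an nr x nc field (used for lattice/controlled placements).
render_disks <- function(nr, nc, centers, r_px, amplitude = 50,
                         background = 5) {
  ys <- matrix(seq_len(nr), nr, nc); xs <- t(matrix(seq_len(nc), nc, nr))
  out <- matrix(background, nr, nc)
  for (i in seq_len(nrow(centers))) {
    d2 <- (ys - centers[i, 1])^2 + (xs - centers[i, 2])^2
    out[d2 <= r_px^2] <- background + amplitude
  }
  out
}
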