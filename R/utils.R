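# Small internal numerics shared across modules.

# Index permutation that moves the zero-lag/zero-frequency sample (position
# 1 in FFT order) to position floor(n/2) + 1.
fftshift_index <- function(n) {
  ((seq_len(n) - 1L + ceiling(n / 2)) %% n) + 1L
}

# Zero-lag position of a centred n-sample axis.
center_index <- function(n) floor(n / 2) + 1L

# Gaussian blur by circular (FFT) convolution with a periodised, unit-sum
# Gaussian kernel. Circular boundaries match the circular autocorrelation
# used downstream; sigma in pixels. sigma = 0 returns the input.
gaussian_blur_fft <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  # centred distances in FFT order along each axis
  dr <- c(0:(nr - 1L)); dr <- pmin(dr, nr - dr)
  dc <- c(0:(nc - 1L)); dc <- pmin(dc, nc - dc)
  kr <- exp(-dr^2 / (2 * sigma_px^2))
  kc <- exp(-dc^2 / (2 * sigma_px^2))
  k <- outer(kr, kc)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / length(x)
}

# Rotate image content by `deg` degrees about the image centre using
# bilinear interpolation on the inverse map. Row index = y (down), column
# index = x (right). Samples outside the source are NA. The convention is
# fixed by the round trip with the phantom generator: a pattern rendered at
# orientation phi is brought to phi = 0 by rotate_bilinear(img, -phi).
rotate_bilinear <- function(x, deg) {
  if (deg %% 360 == 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  th <- -deg * pi / 180
  cy <- (nr - 1) / 2; cx <- (nc - 1) / 2
  # target offsets (0-based coords)
  ty <- rep(seq_len(nr) - 1 - cy, times = nc)
  tx <- rep(seq_len(nc) - 1 - cx, each = nr)
  sx <- cx + tx * cos(th) - ty * sin(th)
  sy <- cy + tx * sin(th) + ty * cos(th)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;   fy <- sy - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 2 & y0 <= nr - 2
  out <- rep(NA_real_, nr * nc)
  i00 <- y0[ok] + 1L + nr * x0[ok]
  v <- (1 - fy[ok]) * (1 - fx[ok]) * x[i00] +
       fy[ok]       * (1 - fx[ok]) * x[i00 + 1L] +
       (1 - fy[ok]) * fx[ok]       * x[i00 + nr] +
       fy[ok]       * fx[ok]       * x[i00 + nr + 1L]
  out[ok] <- v
  matrix(out, nr, nc)
}

# Moving average with window 2h + 1; edges use the partial window so the
# output has the same length and no NA padding.
moving_average <- function(v, halfwidth) {
  h <- as.integer(halfwidth)
  if (h <= 0L) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Vertex offset (in samples, relative to the middle point) of the parabola
# through three equally spaced samples. Returns 0 when the points are
# collinear; the offset is clamped to [-0.5, 0.5].
parabolic_offset <- function(ym, y0, yp) {
  den <- yp - 2 * y0 + ym
  if (!is.finite(den) || den == 0) return(0)
  max(-0.5, min(0.5, (ym - yp) / (2 * den)))
}

# Radial profile of a matrix about a given (row, col) centre (1-based
# indices, possibly fractional): mean of samples whose Euclidean distance
# falls in [k*b, (k+1)*b) pixels; axis at bin centres in micrometres.
# Empty bins are dropped.
radial_profile_about <- function(m, center_rc, bin_width_px, pixel_size_um,
                                 kind) {
  nr <- nrow(m); nc <- ncol(m)
  d <- sqrt(outer((seq_len(nr) - center_rc[1])^2,
                  (seq_len(nc) - center_rc[2])^2, "+"))
  k <- floor(d / bin_width_px)
  means <- vapply(split(as.numeric(m), as.numeric(k)), mean, numeric(1))
  kk <- as.numeric(names(means))
  o <- order(kk)
  profile1d(axis = (kk[o] + 0.5) * bin_width_px * pixel_size_um,
            values = means[o], kind = kind, unit = "um")
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators do not disturb the global stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
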