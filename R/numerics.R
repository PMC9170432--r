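# Grid numerics shared by the level-set, baseline and phantom code.
# Convention: matrices are indexed [row, col]; "x" differences run along rows,
# "y" along columns; boundaries are handled by edge replication (Neumann).

shift_up    <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
shift_down  <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
shift_left  <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
shift_right <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]

# one-sided and central differences (unit grid spacing)
diff_xm <- function(m) m - shift_up(m)          # backward, rows
diff_xp <- function(m) shift_down(m) - m        # forward, rows
diff_ym <- function(m) m - shift_left(m)
diff_yp <- function(m) shift_right(m) - m
diff_xc <- function(m) (shift_down(m) - shift_up(m)) / 2
diff_yc <- function(m) (shift_right(m) - shift_left(m)) / 2

grad_mag_central <- function(m) sqrt(diff_xc(m)^2 + diff_yc(m)^2)

# mean curvature of the level sets of phi, central differences,
# kappa = div(grad phi / |grad phi|)
curvature_2d <- function(phi, eps = 1e-8) {
  px <- diff_xc(phi); py <- diff_yc(phi)
  pxx <- shift_down(phi) - 2 * phi + shift_up(phi)
  pyy <- shift_right(phi) - 2 * phi + shift_left(phi)
  pxy <- (shift_right(shift_down(phi)) - shift_left(shift_down(phi)) -
          shift_right(shift_up(phi)) + shift_left(shift_up(phi))) / 4
  num <- pxx * py^2 - 2 * px * py * pxy + pyy * px^2
  den <- (px^2 + py^2)^1.5 + eps
  k <- num / den
  # curvature of a 1-pixel feature is O(1); clip to the stable stencil range
  pmin(pmax(k, -1), 1)
}

# upwind gradient magnitudes (Osher-Sethian): nabla_plus for speeds > 0,
# nabla_minus for speeds < 0
upwind_grad <- function(phi) {
  a <- diff_xm(phi); b <- diff_xp(phi)
  c <- diff_ym(phi); d <- diff_yp(phi)
  plus <- sqrt(pmax(a, 0)^2 + pmin(b, 0)^2 + pmax(c, 0)^2 + pmin(d, 0)^2)
  minus <- sqrt(pmin(a, 0)^2 + pmax(b, 0)^2 + pmin(c, 0)^2 + pmax(d, 0)^2)
  list(plus = plus, minus = minus)
}

# Separable Gaussian smoothing with edge replication. Works for any kernel /
# image size ratio (radius is clamped to the image).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, min(ceiling(3 * sigma), nrow(m) - 1L, ncol(m) - 1L))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_rows <- function(mm) {
    out <- matrix(0, nrow(mm), ncol(mm))
    idx_base <- seq_len(nrow(mm))
    for (j in -r:r) {
      idx <- pmin(pmax(idx_base + j, 1L), nrow(mm))
      out <- out + k[j + r + 1L] * mm[idx, , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

# Signed distance to the boundary of a binary region: negative inside.
# Euclidean distance transforms via EBImage::distmap; the half-pixel offset
# keeps the zero level on the region boundary.
signed_distance <- function(mask) {
  mask <- (mask > 0) * 1
  if (all(mask == 1)) return(matrix(-1e6, nrow(mask), ncol(mask)))
  if (all(mask == 0)) return(matrix(1e6, nrow(mask), ncol(mask)))
  d_in <- as.matrix(EBImage::distmap(mask, metric = "euclidean"))
  d_out <- as.matrix(EBImage::distmap(1 - mask, metric = "euclidean"))
  # half-pixel shift puts the zero level between the two boundary pixel
  # layers, so |grad phi| ~ 1 across the interface
  ifelse(mask == 1, -(d_in - 0.5), d_out - 0.5)
}

# Bilinear interpolation of matrix m at fractional (row, col) coordinates.
bilinear <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}
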