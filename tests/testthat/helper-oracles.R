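# Independent oracles used across tests. These deliberately avoid the
# package's own vectorized code paths: plain scalar loops and closed forms.

# posterior responsibilities by direct per-term arithmetic
scalar_estep_oracle <- function(x, pi, mu, sigma2) {
  M <- length(x); L <- length(pi)
  r <- matrix(0, M, L)
  for (i in seq_len(M)) {
    num <- numeric(L)
    for (l in seq_len(L))
      num[l] <- pi[l] * exp(-(x[i] - mu[l])^2 / (2 * sigma2[l])) /
        sqrt(2 * pi_const * sigma2[l])
    r[i, ] <- num / sum(num)
  }
  r
}
pi_const <- base::pi

# AUC by exhaustive positive-negative pair enumeration, ties counting 1/2
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# binary disk image on a flat background
disk_image <- function(n = 48, center = c(n / 2, n / 2), radius = n / 4,
                       fg = 200, bg = 50) {
  r <- matrix(seq_len(n), n, n)
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  inside <- (r - center[1])^2 + (c - center[2])^2 <= radius^2
  list(image = ifelse(inside, fg, bg), mask = inside * 1L)
}

# 4-neighbor boundary length of a binary mask
mask_perimeter <- function(m) {
  sum(m[-1, ] != m[-nrow(m), ]) + sum(m[, -1] != m[, -ncol(m)])
}

# binary dilation by one 4-neighborhood step
dilate1 <- function(m) {
  up <- rbind(m[-1, ], m[nrow(m), ]); dn <- rbind(m[1, ], m[-nrow(m), ])
  le <- cbind(m[, -1], m[, ncol(m)]); ri <- cbind(m[, 1], m[, -ncol(m)])
  (m | up | dn | le | ri) * 1
}

# boundary pixels of a mask (inside, adjacent to outside)
mask_boundary <- function(m) {
  er <- 1 - dilate1(1 - m)
  (m == 1) & (er == 0)
}
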