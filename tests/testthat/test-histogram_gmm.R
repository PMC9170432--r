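test_that("build_histogram bins correctly, conserves counts, and validates input", {
  # degenerate single-value image: all mass in one bin
  h <- build_histogram(matrix(7, 10, 10), n_bins = 8)
  expect_equal(sum(h$counts == 100), 1)
  expect_equal(sum(h$counts), 100)

  # 3x3 image of 0..8 into three bins of [0,9)
  h <- build_histogram(matrix(0:8, 3, 3), n_bins = 3, range = c(0, 9))
  expect_equal(h$counts, c(3L, 3L, 3L))

  # value equal to the upper range limit lands in the last (closed) bin
  h <- build_histogram(c(0, 5, 10), n_bins = 2, range = c(0, 10))
  expect_equal(h$counts, c(1L, 2L))

  # conservation under NaN/Inf pixels, random images
  set.seed(4)
  for (k in 1:5) {
    img <- matrix(rnorm(400, 100, 30), 20, 20)
    img[sample(400, 17)] <- NA
    h <- build_histogram(img, n_bins = sample(1:64, 1))
    expect_identical(sum(h$counts), sum(is.finite(img)))
  }

  expect_error(build_histogram(matrix(NA_real_, 2, 2)),
               class = "histoseg_invalid_input")
  expect_error(build_histogram(1:5, n_bins = 4, range = c(5, 1)),
               class = "histoseg_invalid_input")
})

test_that("gaussian_pdf matches the closed form and is symmetric", {
  expect_equal(gaussian_pdf(0, 0, 1), 0.3989422804, tolerance = 1e-9)
  for (mu in c(-3, 0, 11)) for (s2 in c(0.25, 1, 9))
    expect_equal(gaussian_pdf(mu, mu, s2), 1 / sqrt(2 * pi * s2))
  d <- runif(5, 0, 4)
  expect_equal(gaussian_pdf(2 + d, 2, 3), gaussian_pdf(2 - d, 2, 3))
  expect_error(gaussian_pdf(0, 0, 0), class = "histoseg_invalid_param")
  expect_error(gaussian_pdf(0, 0, -1), class = "histoseg_invalid_param")
})

test_that("mixture_density reduces to single components, is symmetric, and integrates to 1", {
  p1 <- gmm_params(1, 5, 4)
  x <- seq(-5, 15, length.out = 101)
  expect_equal(mixture_density(x, p1), gaussian_pdf(x, 5, 4))

  p2 <- gmm_params(c(0.5, 0.5), c(-2, 2), c(1, 1))  # symmetric about 0
  expect_equal(mixture_density(1.3, p2), mixture_density(-1.3, p2))

  # trapezoidal quadrature over a wide grid
  set.seed(11)
  for (k in 1:5) {
    L <- sample(1:3, 1)
    pi_ <- runif(L); pi_ <- pi_ / sum(pi_)
    p <- gmm_params(pi_, runif(L, -50, 50), runif(L, 1, 100))
    lo <- min(p$mu) - 8 * sqrt(max(p$sigma2))
    hi <- max(p$mu) + 8 * sqrt(max(p$sigma2))
    g <- seq(lo, hi, length.out = 4001)
    f <- mixture_density(g, p)
    integral <- sum((f[-1] + f[-length(f)]) / 2) * diff(g[1:2])
    expect_equal(integral, 1, tolerance = 1e-3)
  }
})

test_that("E-step equals scalar per-term arithmetic and trivial symmetries", {
  # identical components: responsibilities equal the mixing coefficients
  p <- gmm_params(c(0.3, 0.7), c(10, 10 + 1e-13), c(4, 4))
  r <- e_step_responsibilities(sample_set(c(1, 5, 20)), p)
  expect_equal(unname(r[, 1]), rep(0.3, 3), tolerance = 1e-9)

  # midpoint of two equal-weight equal-variance components
  p <- gmm_params(c(0.5, 0.5), c(0, 10), c(9, 9))
  r <- e_step_responsibilities(sample_set(5), p)
  expect_equal(as.numeric(r), c(0.5, 0.5))

  # scalar oracle on small random instances, to 1e-12
  set.seed(21)
  for (k in 1:20) {
    M <- sample(1:5, 1); L <- sample(2:3, 1)
    pi_ <- runif(L); pi_ <- pi_ / sum(pi_)
    mu <- sort(runif(L, 0, 100)) + seq_len(L) * 0.01
    s2 <- runif(L, 1, 50)
    x <- runif(M, -20, 120)
    p <- gmm_params(pi_, mu, s2)
    r <- e_step_responsibilities(sample_set(x), p)
    expect_equal(r, scalar_estep_oracle(x, p$pi, p$mu, p$sigma2),
                 tolerance = 1e-12)
    expect_equal(rowSums(r), rep(1, M), tolerance = 1e-9)
  }

  # far-tail samples never divide by zero thanks to log-space computation
  p <- gmm_params(c(0.5, 0.5), c(0, 1), c(1e-4, 1e-4))
  r <- e_step_responsibilities(sample_set(1e6), p)
  expect_true(all(is.finite(r)))
  expect_equal(rowSums(r), 1)
})

test_that("M-step reproduces weighted-average arithmetic and handles collapse", {
  # L = 1 closed form: weighted mean and biased variance
  x <- c(2, 4, 4, 10); w <- c(1, 2, 1, 1)
  s <- sample_set(x, w)
  upd <- m_step_update(s, matrix(1, 4, 1))
  expect_equal(upd$pi, 1)
  expect_equal(upd$mu, weighted.mean(x, w))
  expect_equal(upd$sigma2, sum(w * (x - weighted.mean(x, w))^2) / sum(w))

  # fixed 4x2 responsibilities against hand arithmetic
  r <- matrix(c(0.9, 0.6, 0.2, 0.1,
                0.1, 0.4, 0.8, 0.9), 4, 2)
  x <- c(1, 3, 7, 9)
  s <- sample_set(x)
  upd <- m_step_update(s, r, sigma2_floor = 1e-9)
  n1 <- sum(r[, 1]); n2 <- sum(r[, 2])
  mu1 <- sum(r[, 1] * x) / n1; mu2 <- sum(r[, 2] * x) / n2
  expect_equal(upd$pi, c(n1 / 4, n2 / 4))
  expect_equal(upd$mu, c(mu1, mu2))
  expect_equal(upd$sigma2, c(sum(r[, 1] * (x - mu1)^2) / n1,
                             sum(r[, 2] * (x - mu2)^2) / n2))
  expect_equal(sum(upd$pi), 1, tolerance = 1e-9)

  # all-mass-on-one-component triggers the reseed path, not a crash
  r <- cbind(rep(1, 4), rep(0, 4))
  expect_message(upd <- m_step_update(s, r), "reseeded")
  expect_equal(upd$L, 2L)
  expect_equal(sum(upd$pi), 1, tolerance = 1e-9)
})

test_that("log-likelihood matches closed forms and is linear in weights", {
  p <- gmm_params(1, 3, 1)
  expect_equal(log_likelihood(sample_set(3), p), log(1 / sqrt(2 * pi)),
               tolerance = 1e-9)
  set.seed(5)
  x <- rnorm(50, 3, 2)
  p2 <- gmm_params(c(0.4, 0.6), c(1, 6), c(2, 3))
  expect_equal(log_likelihood(sample_set(x, rep(2, 50)), p2),
               2 * log_likelihood(sample_set(x), p2))
})

test_that("Q-function: scalar expansion, equality at L = 1, and M-step ascent", {
  x <- c(1, 4, 6); s <- sample_set(x)
  p <- gmm_params(c(0.25, 0.75), c(2, 5), c(1, 4))
  r <- e_step_responsibilities(s, p)
  # term-by-term scalar expansion
  q_manual <- 0
  for (i in 1:3) for (l in 1:2)
    q_manual <- q_manual + r[i, l] *
      (log(p$pi[l]) + dnorm(x[i], p$mu[l], sqrt(p$sigma2[l]), log = TRUE))
  expect_equal(q_function(s, p, r), q_manual, tolerance = 1e-12)

  # L = 1: no latent uncertainty, Q equals the log-likelihood
  p1 <- gmm_params(1, 3, 2)
  r1 <- matrix(1, 3, 1)
  expect_equal(q_function(s, p1, r1), log_likelihood(s, p1))

  # the M-step output does not decrease Q at fixed responsibilities
  p_new <- m_step_update(s, r, sigma2_floor = 1e-9)
  expect_gte(q_function(s, p_new, r), q_function(s, p, r) - 1e-10)
})

test_that("EM fits: single-Gaussian closed form and seeded parameter recovery", {
  # L = 1 recovers the weighted mean/variance immediately
  x <- c(1, 2, 6, 9); w <- c(1, 3, 1, 2)
  fit <- fit_gmm_em(sample_set(x, w), 1)
  expect_equal(fit$params$mu, weighted.mean(x, w), tolerance = 1e-9)
  expect_equal(fit$params$sigma2,
               sum(w * (x - weighted.mean(x, w))^2) / sum(w), tolerance = 1e-8)

  # two-component recovery at the generator's known parameters
  truth <- gmm_params(c(0.4, 0.6), c(30, 120), c(100, 225))
  sim <- simulate_gmm_samples(truth, 10000, seed = 99)
  fit <- fit_gmm_em(sim$samples, 2)
  expect_true(fit$trace$converged)
  expect_lt(max(abs(fit$params$mu - truth$mu)), 2)
  expect_lt(max(abs(fit$params$pi - truth$pi)), 0.03)
  expect_equal(sum(fit$params$pi), 1, tolerance = 1e-9)
})

test_that("EM log-likelihood trace is nondecreasing across varied fits", {
  set.seed(31)
  for (k in 1:8) {
    L <- sample(1:3, 1)
    x <- c(rnorm(300, 20, 5), rnorm(200, 60, 8), rnorm(100, 100, 12))
    fit <- fit_gmm_em(sample_set(sample(x, 350)), L,
                      em_config(seed = k, init_method =
                                  sample(c("range", "quantile", "kmeans"), 1)))
    ll <- fit$trace$log_likelihood_per_iter
    expect_true(all(diff(ll) >= -1e-8))
  }
})

test_that("fitting a fine histogram agrees with fitting the raw samples", {
  truth <- gmm_params(c(0.35, 0.65), c(40, 110), c(64, 144))
  sim <- simulate_gmm_samples(truth, 8000, seed = 17)
  fit_raw <- fit_gmm_em(sim$samples, 2)
  h <- build_histogram(sim$samples$values, n_bins = 2000)
  fit_hist <- fit_gmm_em(h, 2)
  bin_w <- diff(h$bin_edges[1:2])
  expect_lt(max(abs(fit_raw$params$mu - fit_hist$params$mu)), 5 * bin_w)
  expect_lt(max(abs(fit_raw$params$pi - fit_hist$params$pi)), 0.01)
  expect_lt(max(abs(sqrt(fit_raw$params$sigma2) - sqrt(fit_hist$params$sigma2))),
            5 * bin_w)
})

test_that("EM attains the optimum of a dense grid search on a constrained subproblem", {
  truth <- gmm_params(c(0.5, 0.5), c(20, 80), c(25, 25))
  sim <- simulate_gmm_samples(truth, 2000, seed = 7)
  fit <- fit_gmm_em(sim$samples, 2)
  ll_em <- tail(fit$trace$log_likelihood_per_iter, 1)
  # grid over both means with pi and sigma2 frozen at the EM solution:
  # no grid point may beat the EM optimum (beyond tolerance)
  mus1 <- seq(fit$params$mu[1] - 3, fit$params$mu[1] + 3, by = 0.05)
  mus2 <- seq(fit$params$mu[2] - 3, fit$params$mu[2] + 3, by = 0.05)
  best_grid <- -Inf
  for (m1 in mus1) {
    for (m2 in mus2) {
      p <- gmm_params(fit$params$pi, c(m1, m2), fit$params$sigma2)
      best_grid <- max(best_grid, log_likelihood(sim$samples, p))
    }
  }
  expect_lte(best_grid, ll_em + 1e-6)
  expect_equal(best_grid, ll_em, tolerance = 1e-6)
})

test_that("EM errors when L exceeds the number of distinct values", {
  expect_error(fit_gmm_em(sample_set(c(1, 1, 2, 2)), 3),
               class = "histoseg_invalid_input")
})

test_that("BIC component selection finds the generative component count", {
  truth2 <- gmm_params(c(0.45, 0.55), c(30, 120), c(100, 150))
  sim2 <- simulate_gmm_samples(truth2, 4000, seed = 13)
  sel2 <- select_components(sim2$samples, 1:4)
  expect_identical(sel2$best_L, 2L)

  sim1 <- simulate_gmm_samples(gmm_params(1, 50, 100), 4000, seed = 13)
  sel1 <- select_components(sim1$samples, 1:3)
  expect_identical(sel1$best_L, 1L)

  # singleton candidate list: no choice to make
  expect_identical(select_components(sim2$samples, 3L)$best_L, 3L)
})

test_that("EM solution agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  truth <- gmm_params(c(0.4, 0.6), c(30, 120), c(100, 225))
  sim <- simulate_gmm_samples(truth, 5000, seed = 55)
  fit <- fit_gmm_em(sim$samples, 2, em_config(tol = 1e-10))
  mc <- Mclust(sim$samples$values, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$params$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.01)
  expect_equal(tail(fit$trace$log_likelihood_per_iter, 1), mc$loglik,
               tolerance = 1e-4)
})

test_that("histogram CSV and mixture JSON round-trip", {
  h <- build_histogram(matrix(rnorm(100, 50, 10), 10, 10), n_bins = 16)
  f <- tempfile(fileext = ".csv")
  write_histogram_csv(h, f)
  s <- read_histogram_csv(f)
  expect_equal(s$M, h$total)
  expect_equal(s$values, h$mids[h$counts > 0], tolerance = 1e-9)

  p <- gmm_params(c(0.2, 0.8), c(10, 90), c(4, 16))
  g <- tempfile(fileext = ".json")
  write_gmm_json(p, g)
  p2 <- read_gmm_json(g)
  expect_equal(p2$pi, p$pi)
  expect_equal(p2$mu, p$mu)
  expect_equal(p2$sigma2, p$sigma2)
})
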