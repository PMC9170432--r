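#' Univariate Gaussian density
#'
#' Thin validated wrapper around the normal density used throughout the
#' mixture model; parameterized by variance, matching the mixture component
#' parameterization.
#'
#' @param x numeric vector of evaluation points.
#' @param mu mean (intensity units).
#' @param sigma2 variance (intensity units squared), strictly positive.
#' @param log if TRUE return the log-density.
#' @return Nonnegative density values (or log-densities).
#' @export
gaussian_pdf <- function(x, mu, sigma2, log = FALSE) {
  if (!is.finite(sigma2) || sigma2 <= 0)
    abort_invalid_param("'sigma2' must be strictly positive")
  dnorm(x, mean = mu, sd = sqrt(sigma2), log = log)
}

#' Gaussian mixture parameter set
#'
#' The full parameter set of an L-component univariate mixture over image
#' intensity: mixing coefficients \eqn{\pi_l} (summing to 1), means
#' \eqn{\mu_l} and variances \eqn{\sigma^2_l}. Components are kept in
#' canonical order, ascending by mean, so that e.g. "the brightest component"
#' is a stable notion across runs.
#'
#' @param pi mixing coefficients, nonnegative, summing to 1 (within 1e-9 they
#'   are renormalized exactly).
#' @param mu component means.
#' @param sigma2 component variances, strictly positive.
#' @return An object of class \code{gmm_params} with fields \code{pi},
#'   \code{mu}, \code{sigma2} and \code{L}.
#' @examples
#' p <- gmm_params(pi = c(0.4, 0.6), mu = c(30, 120), sigma2 = c(100, 225))
#' @export
gmm_params <- function(pi, mu, sigma2) {
  pi <- as.numeric(pi); mu <- as.numeric(mu); sigma2 <- as.numeric(sigma2)
  L <- length(mu)
  if (L < 1L || length(pi) != L || length(sigma2) != L)
    abort_invalid_param("'pi', 'mu', 'sigma2' must have equal positive length")
  if (any(!is.finite(c(pi, mu, sigma2))))
    abort_invalid_param("mixture parameters must be finite")
  if (any(pi < -1e-12) || any(pi > 1 + 1e-12))
    abort_invalid_param("mixing coefficients must lie in [0, 1]")
  if (abs(sum(pi) - 1) > 1e-9)
    abort_invalid_param("mixing coefficients must sum to 1")
  pi <- pmin(pmax(pi, 0), 1); pi <- pi / sum(pi)
  if (any(sigma2 <= 0))
    abort_invalid_param("variances must be strictly positive")
  o <- order(mu)
  structure(list(pi = pi[o], mu = mu[o], sigma2 = sigma2[o], L = L),
            class = "gmm_params")
}

#' @export
print.gmm_params <- function(x, ...) {
  cat(sprintf("<gmm_params> L = %d components (ascending mean)\n", x$L))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
as.data.frame.gmm_params <- function(x, ...) {
  data.frame(component = seq_len(x$L), pi = x$pi, mu = x$mu, sigma2 = x$sigma2)
}

#' Mixture probability density
#'
#' Evaluates \eqn{\rho(x) = \sum_l \pi_l N(x; \mu_l, \sigma^2_l)}.
#'
#' @param x numeric vector.
#' @param params a \code{gmm_params}.
#' @param log if TRUE return the log-density (computed by log-sum-exp).
#' @return Density values at \code{x}.
#' @export
mixture_density <- function(x, params, log = FALSE) {
  stopifnot(inherits(params, "gmm_params"))
  ld <- component_log_densities(x, params)   # n x L, includes log pi
  out <- log_sum_exp_rows(ld)
  if (log) out else exp(out)
}

# n x L matrix of log(pi_l) + log N(x_i; mu_l, sigma2_l)
component_log_densities <- function(x, params) {
  n <- length(x)
  ld <- matrix(0, n, params$L)
  for (l in seq_len(params$L)) {
    ld[, l] <- log(params$pi[l] + .Machine$double.xmin) +
      dnorm(x, params$mu[l], sqrt(params$sigma2[l]), log = TRUE)
  }
  ld
}

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' E-step: posterior responsibilities
#'
#' Computes the posterior probability that each sample arose from each
#' component,
#' \eqn{r_{il} = \pi_l N(x_i;\mu_l,\sigma^2_l) / \sum_k \pi_k N(x_i;\mu_k,\sigma^2_k)},
#' in log space so that far-tail samples never divide by zero.
#'
#' @param samples a \code{sample_set} (or anything \code{\link{as_sample_set}}
#'   accepts).
#' @param params a \code{gmm_params}.
#' @return An M x L matrix of responsibilities; every row sums to 1.
#' @export
e_step_responsibilities <- function(samples, params) {
  samples <- as_sample_set(samples)
  ld <- component_log_densities(samples$values, params)
  lse <- log_sum_exp_rows(ld)
  exp(ld - lse)
}

#' M-step: maximum-likelihood parameter updates
#'
#' Given responsibilities, returns the responsibility-weighted updates: mixing
#' coefficients are mean responsibilities, means are responsibility-weighted
#' sample means, variances are responsibility-weighted squared deviations
#' about the new means (floored at \code{sigma2_floor}). A component whose
#' effective count vanishes is reseeded at the sample the current mixture
#' explains worst (lowest mixture density) rather than crashing.
#'
#' @param samples a \code{sample_set}.
#' @param resp M x L responsibility matrix (rows summing to 1).
#' @param sigma2_floor lower bound on variances; default
#'   \code{1e-6 * diff(range(values))^2}.
#' @return A \code{gmm_params}. Note the canonical mean-ordering is applied,
#'   so columns of \code{resp} may correspond to permuted components of the
#'   output; use \code{\link{fit_gmm_em}} for order-consistent iteration.
#' @export
m_step_update <- function(samples, resp, sigma2_floor = NULL) {
  samples <- as_sample_set(samples)
  resp <- as.matrix(resp)
  if (nrow(resp) != length(samples$values))
    abort_invalid_input("responsibility rows must match the number of samples")
  if (max(abs(rowSums(resp) - 1)) > 1e-6)
    abort_invalid_input("responsibility rows must sum to 1")
  if (is.null(sigma2_floor))
    sigma2_floor <- default_sigma2_floor(samples$values)
  upd <- m_step_raw(samples, resp, sigma2_floor)
  gmm_params(upd$pi, upd$mu, upd$sigma2)
}

# Unordered update used internally by the EM loop (keeps component identity
# aligned with responsibility columns between iterations).
m_step_raw <- function(samples, resp, sigma2_floor) {
  x <- samples$values; w <- samples$weights; M <- samples$M
  L <- ncol(resp)
  wr <- resp * w                       # M x L of w_i * r_il
  Nl <- colSums(wr)                    # effective counts
  pi_new <- Nl / M
  mu_new <- numeric(L); s2_new <- numeric(L)
  for (l in seq_len(L)) {
    if (Nl[l] <= M * 1e-12) {
      # degenerate component: reseed at the worst-explained sample
      dens <- rowSums(wr)              # proxy for mixture support at x_i
      i0 <- which.min(dens / pmax(w, .Machine$double.eps))
      message(sprintf(
        "m_step: component %d collapsed (effective count %.3g); reseeded at x = %g",
        l, Nl[l], x[i0]))
      mu_new[l] <- x[i0]
      s2_new[l] <- max(var_or_zero(x, w), sigma2_floor)
      pi_new[l] <- 1 / M
    } else {
      mu_new[l] <- sum(wr[, l] * x) / Nl[l]
      s2_new[l] <- max(sum(wr[, l] * (x - mu_new[l])^2) / Nl[l], sigma2_floor)
    }
  }
  pi_new <- pi_new / sum(pi_new)
  list(pi = pi_new, mu = mu_new, sigma2 = s2_new)
}

var_or_zero <- function(x, w) {
  m <- weighted.mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

default_sigma2_floor <- function(values) {
  r <- diff(range(values))
  if (r <= 0) r <- max(abs(values), 1)
  1e-6 * r^2
}

#' Log-likelihood of a sample set under a mixture
#'
#' \eqn{K(\alpha) = \sum_i w_i \log \rho(x_i)}, computed via log-sum-exp.
#'
#' @inheritParams e_step_responsibilities
#' @return A single number.
#' @export
log_likelihood <- function(samples, params) {
  samples <- as_sample_set(samples)
  sum(samples$weights * mixture_density(samples$values, params, log = TRUE))
}

#' EM Q-function (expected complete-data log-likelihood)
#'
#' \eqn{Q = \sum_l \sum_i w_i r_{il} (\log\pi_l + \log N(x_i;\mu_l,\sigma^2_l))},
#' evaluated at new parameters with responsibilities held at their previous
#' values. The M-step maximizes this quantity, which is what drives the EM
#' monotonicity guarantee.
#'
#' @param samples a \code{sample_set}.
#' @param params_new a \code{gmm_params} at which to evaluate.
#' @param resp_old responsibility matrix from the previous E-step.
#' @return A single number.
#' @export
q_function <- function(samples, params_new, resp_old) {
  samples <- as_sample_set(samples)
  resp_old <- as.matrix(resp_old)
  ld <- component_log_densities(samples$values, params_new)
  sum(samples$weights * rowSums(resp_old * ld))
}

#' EM fitting configuration
#'
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param sigma2_floor variance floor; \code{NULL} (default) means
#'   \code{1e-6 * (data range)^2}, the classical guard against a component
#'   collapsing onto a single intensity.
#' @param seed RNG seed governing any stochastic initialization.
#' @param init_method one of \code{"range"} (deterministic, the default:
#'   means evenly spaced between the 1st and 99th weighted percentiles, so a
#'   small high- or low-intensity class such as a lesion always has a nearby
#'   starting component), \code{"quantile"} (evenly spaced mass quantiles),
#'   \code{"kmeans"}, \code{"random"}, or \code{"best"} (multi-start: run EM
#'   from the range, quantile and kmeans initializations and keep the
#'   highest-likelihood fit; deterministic given the seed).
#' @return An object of class \code{em_config}.
#' @export
em_config <- function(max_iter = 500L, tol = 1e-6, sigma2_floor = NULL,
                      seed = 1L,
                      init_method = c("range", "quantile", "kmeans", "random",
                                      "best")) {
  init_method <- match.arg(init_method)
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) abort_config("'max_iter' must be >= 1")
  if (!is.finite(tol) || tol <= 0) abort_config("'tol' must be positive")
  if (!is.null(sigma2_floor) && (!is.finite(sigma2_floor) || sigma2_floor <= 0))
    abort_config("'sigma2_floor' must be positive")
  structure(list(max_iter = max_iter, tol = tol, sigma2_floor = sigma2_floor,
                 seed = as.integer(seed), init_method = init_method),
            class = "em_config")
}

init_gmm <- function(samples, L, config) {
  x <- samples$values; w <- samples$weights
  pooled <- max(var_or_zero(x, w), default_sigma2_floor(x))
  mu <- switch(config$init_method,
    range = {
      q <- weighted_quantile(x, w, probs = c(0.01, 0.99))
      if (q[1] >= q[2]) q <- range(x)
      if (L == 1L) mean(q) else seq(q[1], q[2], length.out = L)
    },
    quantile = {
      m <- weighted_quantile(x, w, probs = (2 * seq_len(L) - 1) / (2 * L))
      # heavily concentrated (e.g. few-valued) data collapses quantiles;
      # fall back to evenly spaced means over the range
      if (anyDuplicated(m)) m <- seq(min(x), max(x), length.out = L)
      m
    },
    kmeans = {
      set.seed(config$seed)
      if (length(unique(x)) <= L) sort(unique(x))[seq_len(L)]
      else sort(suppressWarnings(
        kmeans(x, centers = L, nstart = 3, iter.max = 100L))$centers[, 1])
    },
    random = {
      set.seed(config$seed)
      sort(sample(x, L, prob = w / sum(w), replace = length(x) < L))
    })
  # jitter exact ties between initial means so components can separate
  if (anyDuplicated(mu)) mu <- mu + seq_len(L) * 1e-6 * (diff(range(x)) + 1)
  list(pi = rep(1 / L, L), mu = mu, sigma2 = rep(pooled, L))
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  sapply(probs, function(p) x[which(cw >= p)[1]])
}

#' Fit a Gaussian mixture to samples or a histogram by EM
#'
#' Alternates \code{\link{e_step_responsibilities}} and the M-step until the
#' relative change in log-likelihood drops below \code{config$tol} or
#' \code{config$max_iter} is reached. A histogram enters with bin centers as
#' values and counts as weights, so the histogram fit is exact weighted
#' maximum likelihood. Components in the result are in canonical ascending-mean
#' order.
#'
#' @param samples a \code{sample_set}, \code{intensity_histogram}, or raw
#'   numeric vector/matrix of intensities.
#' @param L number of components (>= 1); must not exceed the number of
#'   distinct sample values.
#' @param config an \code{\link{em_config}}.
#' @return An object of class \code{gmm_fit}: list with \code{params}
#'   (\code{gmm_params}), \code{responsibilities} (M x L matrix),
#'   \code{trace} (per-iteration log-likelihood and Q values, \code{n_iter},
#'   \code{converged}), \code{samples}, and the \code{config} used.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(400, 30, 10), rnorm(600, 120, 15))
#' fit <- fit_gmm_em(x, L = 2)
#' fit$params
#' @export
fit_gmm_em <- function(samples, L, config = em_config()) {
  samples <- as_sample_set(samples)
  L <- as.integer(L)
  if (is.na(L) || L < 1L) abort_invalid_input("'L' must be a positive integer")
  if (L > length(unique(samples$values)))
    abort_invalid_input(sprintf(
      "L = %d exceeds the number of distinct sample values (%d)",
      L, length(unique(samples$values))))
  if (config$init_method == "best") {
    fits <- lapply(c("range", "quantile", "kmeans"), function(im) {
      cfg <- config; cfg$init_method <- im
      fit_gmm_em(samples, L, cfg)
    })
    lls <- vapply(fits, function(f)
      tail(f$trace$log_likelihood_per_iter, 1), numeric(1))
    best <- fits[[which.max(lls)]]
    best$config <- config
    return(best)
  }
  floor2 <- if (is.null(config$sigma2_floor))
    default_sigma2_floor(samples$values) else config$sigma2_floor

  par <- init_gmm(samples, L, config)
  params <- gmm_params_unchecked(par)
  ll_trace <- numeric(0)
  q_trace <- numeric(0)
  converged <- FALSE
  resp <- NULL
  ll_old <- -Inf
  iter <- 0L
  for (iter in seq_len(config$max_iter)) {
    ld <- component_log_densities(samples$values, params)
    lse <- log_sum_exp_rows(ld)
    resp <- exp(ld - lse)
    ll <- sum(samples$weights * lse)
    ll_trace <- c(ll_trace, ll)
    upd <- m_step_raw(samples, resp, floor2)
    params <- gmm_params_unchecked(upd)
    q_trace <- c(q_trace, q_function(samples, params, resp))
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= config$tol * (abs(ll_old) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # canonical ordering of the final state, responsibilities re-derived so
  # their columns match the ordered components
  o <- order(params$mu)
  params <- gmm_params(params$pi[o], params$mu[o], params$sigma2[o])
  resp <- e_step_responsibilities(samples, params)
  structure(list(params = params,
                 responsibilities = resp,
                 trace = list(log_likelihood_per_iter = ll_trace,
                              q_values_per_iter = q_trace,
                              n_iter = iter, converged = converged),
                 samples = samples, config = config),
            class = "gmm_fit")
}

# internal: skip ordering/validation during iteration (columns of resp must
# stay aligned with components)
gmm_params_unchecked <- function(par) {
  structure(list(pi = par$pi, mu = par$mu, sigma2 = par$sigma2,
                 L = length(par$mu)), class = "gmm_params")
}

#' @export
print.gmm_fit <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("<gmm_fit> L = %d, %d iterations, %s (logL = %.4f)\n",
              x$params$L, tr$n_iter,
              if (tr$converged) "converged" else "NOT converged",
              tail(tr$log_likelihood_per_iter, 1)))
  print(as.data.frame(x$params), digits = 4)
  invisible(x)
}

#' @export
logLik.gmm_fit <- function(object, ...) {
  ll <- tail(object$trace$log_likelihood_per_iter, 1)
  structure(ll, df = 3 * object$params$L - 1, class = "logLik")
}

#' @export
coef.gmm_fit <- function(object, ...) as.data.frame(object$params)

#' Choose the number of mixture components by BIC
#'
#' Fits every candidate L and scores each by the Bayesian information
#' criterion \eqn{-2 \log L + k \log M} with \eqn{k = 3L - 1} free parameters
#' (L means, L variances, L-1 free mixing coefficients). Ties break toward
#' the smaller L. Candidates whose fit fails (e.g. more components than
#' distinct values) are skipped with a warning.
#'
#' @param samples as in \code{\link{fit_gmm_em}}.
#' @param L_candidates vector of candidate component counts.
#' @param config an \code{\link{em_config}}.
#' @return List with \code{best_L}, \code{scores} (BIC per candidate, NA for
#'   failed fits) and \code{fits} (the successful \code{gmm_fit}s).
#' @export
select_components <- function(samples, L_candidates = 1:4, config = em_config()) {
  samples <- as_sample_set(samples)
  if (length(L_candidates) == 0L)
    abort_invalid_input("'L_candidates' must be nonempty")
  L_candidates <- as.integer(L_candidates)
  scores <- rep(NA_real_, length(L_candidates))
  fits <- vector("list", length(L_candidates))
  for (j in seq_along(L_candidates)) {
    L <- L_candidates[j]
    fit <- tryCatch(fit_gmm_em(samples, L, config), error = function(e) {
      warning(sprintf("select_components: L = %d failed (%s); skipped",
                      L, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(fit)) {
      ll <- tail(fit$trace$log_likelihood_per_iter, 1)
      scores[j] <- -2 * ll + (3 * L - 1) * log(samples$M)
      fits[[j]] <- fit
    }
  }
  if (all(is.na(scores)))
    abort_invalid_input("all candidate component counts failed to fit")
  ok <- which(!is.na(scores))
  best <- ok[order(scores[ok], L_candidates[ok])][1]
  list(best_L = L_candidates[best], scores = scores, fits = fits)
}

#' Serialize mixture parameters to JSON
#'
#' The JSON layout is \code{{"components": [{"pi":..., "mu":..., "sigma2":...},
#' ...]}}.
#'
#' @param params a \code{gmm_params}.
#' @param path file path.
#' @return \code{write_gmm_json} returns \code{path} invisibly;
#'   \code{read_gmm_json} returns a \code{gmm_params}.
#' @export
write_gmm_json <- function(params, path) {
  stopifnot(inherits(params, "gmm_params"))
  comps <- lapply(seq_len(params$L), function(l)
    list(pi = params$pi[l], mu = params$mu[l], sigma2 = params$sigma2[l]))
  jsonlite::write_json(list(components = comps), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gmm_json
#' @export
read_gmm_json <- function(path) {
  if (!file.exists(path)) abort_io(paste0("no such file: ", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$components)) abort_io("JSON lacks a 'components' field")
  d <- as.data.frame(j$components)
  gmm_params(d$pi, d$mu, d$sigma2)
}
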