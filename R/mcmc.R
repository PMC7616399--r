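#' Adaptive random-walk Metropolis sampler
#'
#' Componentwise Gaussian random-walk Metropolis on an unconstrained
#' parameter vector. Proposal scales adapt per component during warm-up
#' (Robbins-Monro toward a 0.44 acceptance rate, the componentwise optimum)
#' and are frozen afterwards, so the post-warm-up chain is a valid Markov
#' chain. Two chains with overdispersed starts are the default, matching the
#' convention of running few long chains and judging convergence by
#' split-R-hat and effective sample size.
#'
#' @param log_post Function mapping an unconstrained parameter vector to its
#'   log posterior density (up to a constant); must return `-Inf` outside
#'   the support rather than error.
#' @param init Numeric vector of initial values (unconstrained scale).
#' @param chains,iter,warmup Chains, iterations per chain, and warm-up
#'   iterations discarded from each chain.
#' @param seed Integer seed; chain c uses a substream derived from it.
#' @param init_jitter SD of the Gaussian jitter that overdisperses each
#'   chain's start.
#' @param scale0 Initial proposal sd per component (recycled).
#' @return List with `draws` (array `[iter - warmup, chains, n_par]`),
#'   `accept_rate` per component, and the frozen proposal `scales`.
#' @keywords internal
metropolis_sample <- function(log_post, init, chains = 2L, iter = 2000L,
                              warmup = 1000L, seed = 1L, init_jitter = 0.5,
                              scale0 = 0.2) {
  n_par <- length(init)
  keep <- iter - warmup
  if (keep < 1L) stop("iter must exceed warmup")
  draws <- array(NA_real_, dim = c(keep, chains, n_par))
  acc <- matrix(0, chains, n_par)
  scales_out <- matrix(NA_real_, chains, n_par)
  for (ch in seq_len(chains)) {
    set.seed(derive_seed(seed, 1000L + ch))
    theta <- init + stats::rnorm(n_par, 0, init_jitter)
    lp <- log_post(theta)
    tries <- 0L
    while (!is.finite(lp) && tries < 100L) {
      theta <- init + stats::rnorm(n_par, 0, init_jitter)
      lp <- log_post(theta)
      tries <- tries + 1L
    }
    if (!is.finite(lp)) {
      theta <- init
      lp <- log_post(theta)
      if (!is.finite(lp)) stop("log posterior not finite at init")
    }
    log_scale <- rep(log(scale0), length.out = n_par)
    for (t in seq_len(iter)) {
      for (j in seq_len(n_par)) {
        prop <- theta
        prop[j] <- prop[j] + stats::rnorm(1, 0, exp(log_scale[j]))
        lp_prop <- log_post(prop)
        alpha <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp)) else 0
        if (stats::runif(1) < alpha) {
          theta <- prop
          lp <- lp_prop
          if (t > warmup) acc[ch, j] <- acc[ch, j] + 1
        }
        if (t <= warmup) {
          log_scale[j] <- log_scale[j] + (alpha - 0.44) / t^0.6
        }
      }
      if (t > warmup) draws[t - warmup, ch, ] <- theta
    }
    scales_out[ch, ] <- exp(log_scale)
  }
  list(draws = draws, accept_rate = acc / keep, scales = scales_out)
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends inflate the statistic. Values near 1
#' indicate the chains mix over a common distribution; > 1.05 is the usual
#' warning level.
#'
#' @param x Matrix of draws, iterations x chains (or a vector for one
#'   chain).
#' @return Single numeric R-hat (NaN when the draws are constant).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  split <- cbind(x[seq_len(half), , drop = FALSE],
                 x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(split)
  nn <- nrow(split)
  means <- colMeans(split)
  vars <- apply(split, 2, stats::var)
  w <- mean(vars)
  b <- nn * stats::var(means)
  if (w == 0) return(NaN)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

#' Effective sample size
#'
#' Multi-chain effective sample size from the combined autocorrelation
#' function, truncated by Geyer's initial monotone positive-sequence rule.
#'
#' @inheritParams split_rhat
#' @return Single numeric ESS (capped at the total number of draws).
#' @export
ess <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 4L) return(NaN)
  chain_vars <- apply(x, 2, stats::var)
  w <- mean(chain_vars)
  b_over_n <- stats::var(colMeans(x))
  var_plus <- (n - 1) / n * w + b_over_n
  if (var_plus == 0) return(NaN)
  acov <- function(v, lag) {
    v <- v - mean(v)
    sum(v[seq_len(n - lag)] * v[(lag + 1):n]) / n
  }
  max_lag <- min(n - 2L, 1000L)
  rho <- numeric(max_lag + 1L)
  for (lag in 0:max_lag) {
    rho[lag + 1L] <- 1 - (w - mean(vapply(seq_len(m), function(c)
      acov(x[, c], lag), numeric(1)))) / var_plus
  }
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  tau <- -1
  pair_prev <- Inf
  lag <- 0L
  while (lag + 1L <= max_lag) {
    pair <- rho[lag + 1L] + rho[lag + 2L]
    if (pair < 0) break
    pair <- min(pair, pair_prev)
    tau <- tau + 2 * pair
    pair_prev <- pair
    lag <- lag + 2L
  }
  tau <- max(tau, 1 / (n * m))
  min(n * m / tau, n * m)
}

# Summaries for a draws array [draw, chain, param]
mcmc_diagnostics <- function(draws, par_names) {
  n_par <- dim(draws)[3]
  data.frame(
    parameter = par_names,
    mean = vapply(seq_len(n_par), function(j) mean(draws[, , j]), numeric(1)),
    sd = vapply(seq_len(n_par), function(j) stats::sd(as.vector(draws[, , j])),
                numeric(1)),
    rhat = vapply(seq_len(n_par), function(j) split_rhat(draws[, , j]),
                  numeric(1)),
    ess = vapply(seq_len(n_par), function(j) ess(draws[, , j]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
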