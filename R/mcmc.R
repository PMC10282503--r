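## MCMC machinery: configuration profiles, a generic componentwise
## adaptive random-walk Metropolis sampler over an arbitrary log-posterior,
## the Gelman-Rubin convergence diagnostic, and posterior summaries.
## The full hierarchical CJS model is sampled with the same kernel
## implemented in compiled code (see fit_cjs_community()).

#' MCMC configuration profiles
#'
#' `"full"` is the long production profile (3 chains of 110,000
#' iterations, 10,000 burn-in, thinned by 5: 60,000 kept draws);
#' `"test"` is the scaled-down profile used for simulation studies and
#' routine checking (3 chains of 6,000, burn-in 2,000, thinned by 2).
#'
#' @param profile `"full"` or `"test"`, or a list with fields `chains`,
#'   `iters`, `burnin`, `thin` (passed through after validation).
#' @return list with `chains`, `iters`, `burnin`, `thin`.
#' @export
mcmc_profile <- function(profile = "test") {
  cfg <- if (is.list(profile)) profile
  else switch(profile,
              full = list(chains = 3L, iters = 110000L, burnin = 10000L, thin = 5L),
              test = list(chains = 3L, iters = 6000L, burnin = 2000L, thin = 2L),
              stop("unknown MCMC profile: ", profile, call. = FALSE))
  stopifnot(cfg$chains >= 1L, cfg$iters > cfg$burnin, cfg$thin >= 1L,
            (cfg$iters - cfg$burnin) %% cfg$thin == 0L)
  cfg
}

#' Kept posterior draw count of a configuration
#'
#' @param config an MCMC configuration list (see [mcmc_profile()]).
#' @return total kept draws across chains:
#'   `chains * (iters - burnin) / thin`.
#' @export
kept_draws <- function(config) {
  config <- mcmc_profile(config)
  config$chains * (config$iters - config$burnin) %/% config$thin
}

#' Generic componentwise adaptive Metropolis sampler
#'
#' Samples an arbitrary target density via random-walk
#' Metropolis-within-Gibbs with per-coordinate step sizes adapted toward a
#' target acceptance rate during burn-in (Robbins-Monro), frozen
#' afterwards. Initial values are drawn by `init` until the log-posterior
#' is finite (up to `max_init_tries` attempts per chain).
#'
#' @param logpost function mapping a numeric parameter vector to a scalar
#'   log-density (`-Inf` allowed outside the support).
#' @param init numeric vector of initial values, or a function `(chain)`
#'   returning one.
#' @param config MCMC configuration (see [mcmc_profile()]).
#' @param seed integer seed; chain `c` uses `seed + c - 1`. Identical seed
#'   and configuration give bit-identical draws.
#' @param init_step initial proposal SD.
#' @param target_accept adaptation target acceptance rate.
#' @param max_init_tries initialization attempts per chain.
#' @return object of class `mcmc_draws`: list with `draws` (matrix, kept
#'   iterations stacked over chains, one column per parameter), `chain`
#'   (integer index per row), and the configuration metadata.
#' @export
run_mcmc <- function(logpost, init, config = mcmc_profile("test"), seed = 1L,
                     init_step = 0.5, target_accept = 0.44, max_init_tries = 20L) {
  config <- mcmc_profile(config)
  init_fun <- if (is.function(init)) init else function(chain) init
  all_draws <- list()
  chain_id <- integer(0)
  for (ch in seq_len(config$chains)) {
    set.seed(seed + ch - 1L)
    theta <- NULL
    for (k in seq_len(max_init_tries)) {
      cand <- as.numeric(init_fun(ch))
      if (is.finite(logpost(cand))) { theta <- cand; break }
    }
    if (is.null(theta))
      stop("could not find initial values with finite log-posterior", call. = FALSE)
    P <- length(theta)
    lp <- logpost(theta)
    lstep <- rep(log(init_step), P)
    n_kept <- (config$iters - config$burnin) %/% config$thin
    kept <- matrix(NA_real_, n_kept, P)
    ki <- 0L
    for (it in seq_len(config$iters)) {
      eta <- 10 / (100 + it)
      for (j in seq_len(P)) {
        prop <- theta
        prop[j] <- theta[j] + exp(lstep[j]) * stats::rnorm(1L)
        lp_prop <- logpost(prop)
        aprob <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp)) else 0
        if (stats::runif(1L) < aprob) { theta <- prop; lp <- lp_prop }
        if (it <= config$burnin) lstep[j] <- lstep[j] + eta * (aprob - target_accept)
      }
      if (it > config$burnin && (it - config$burnin) %% config$thin == 0L) {
        ki <- ki + 1L
        kept[ki, ] <- theta
      }
    }
    all_draws[[ch]] <- kept
    chain_id <- c(chain_id, rep(ch, n_kept))
  }
  structure(list(draws = do.call(rbind, all_draws), chain = chain_id,
                 n_chains = config$chains, n_iter = config$iters,
                 n_burnin = config$burnin, thin = config$thin, seed = seed),
            class = "mcmc_draws")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic R-hat from between- and within-chain variances. Values at or
#' above 1.1 flag non-convergence. Chains with zero within-chain variance
#' are degenerate: `NA` is returned with attribute `degenerate = TRUE`.
#'
#' @param x matrix of draws (kept iterations x chains), or a vector with
#'   `chain` supplied.
#' @param chain optional integer chain index per element of `x`.
#' @return scalar R-hat (`NA` if degenerate), with attribute `converged`
#'   (`TRUE` iff finite and < 1.1).
#' @export
rhat <- function(x, chain = NULL) {
  if (!is.matrix(x)) {
    stopifnot(!is.null(chain))
    x <- do.call(cbind, split(x, chain))
  }
  M <- ncol(x); n <- nrow(x)
  if (M < 2L || n < 4L) stop("need >= 2 chains and >= 4 draws per chain", call. = FALSE)
  W <- mean(apply(x, 2L, stats::var))
  if (!is.finite(W) || W == 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    attr(out, "converged") <- FALSE
    return(out)
  }
  B_over_n <- stats::var(colMeans(x))
  r <- sqrt(((n - 1) / n * W + B_over_n) / W)
  attr(r, "degenerate") <- FALSE
  attr(r, "converged") <- is.finite(r) && r < 1.1
  r
}

#' Posterior mean and equal-tailed credible interval
#'
#' @param draws numeric vector, or matrix with parameters in columns.
#' @param ci_level credible mass of the equal-tailed interval
#'   (default 0.89; 0.95 is the conventional alternative).
#' @return data frame with `mean`, `lower`, `upper` (one row per
#'   parameter).
#' @export
posterior_summary <- function(draws, ci_level = 0.89) {
  if (!is.matrix(draws)) draws <- matrix(draws, ncol = 1L)
  stopifnot(nrow(draws) > 0L, ci_level > 0, ci_level < 1)
  a <- (1 - ci_level) / 2
  q <- t(apply(draws, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  out <- data.frame(mean = colMeans(draws), lower = q[, 1L], upper = q[, 2L])
  rownames(out) <- colnames(draws)
  out
}
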