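## Posterior effect indices: probability of direction (pd), sample-based
## highest-density intervals (HDI), and coverage of a region of practical
## equivalence (ROPE), with the categorical decision rules used for
## reporting covariate effects.

#' Probability of direction
#'
#' The posterior probability that a parameter is strictly positive or
#' strictly negative (whichever is larger), in percent. Ranges from 50
#' (sign undecided) to 100. Draws exactly equal to zero count toward
#' neither sign (their number is logged).
#'
#' @param draws numeric posterior draws.
#' @return pd in percent.
#' @export
probability_of_direction <- function(draws) {
  stopifnot(length(draws) > 0L)
  nz <- sum(draws == 0)
  if (nz > 0L) cjs_log("probability_of_direction: %d draws exactly zero", nz)
  100 * max(mean(draws > 0), mean(draws < 0))
}

#' Sample-based highest-density interval
#'
#' The shortest interval containing `ceiling(prob * n)` of the sorted
#' draws; width ties are broken by the earliest window. No density
#' smoothing is involved, so the result is deterministic and brute-force
#' verifiable.
#'
#' @param draws numeric posterior draws.
#' @param prob probability mass of the interval (default 0.89).
#' @return numeric length-2 vector `c(lower, upper)`.
#' @export
hdi <- function(draws, prob = 0.89) {
  n <- length(draws)
  k <- ceiling(prob * n)
  stopifnot(k >= 2L, n >= k)
  x <- sort(draws)
  widths <- x[k:n] - x[1:(n - k + 1L)]
  i <- which.min(widths)          # which.min takes the first minimum
  c(x[i], x[i + k - 1L])
}

#' ROPE coverage and significance category
#'
#' Computes the percentage of the HDI's draws lying inside the region of
#' practical equivalence `[-rope_halfwidth, +rope_halfwidth]` and applies
#' the decision rules: < 1% in ROPE is `"significant"`, < 2.5%
#' `"probably significant"`, 100% (HDI fully inside the ROPE)
#' `"null-accepted"`, anything else `"undecided"`. For standardized
#' predictors on the logit scale the default half-width is 0.1.
#'
#' @param draws numeric posterior draws.
#' @param rope_halfwidth half-width of the ROPE (default 0.1).
#' @param hdi_prob probability mass of the HDI used (default 0.89).
#' @param within_hdi compute the percentage over draws inside the HDI
#'   (default, the convention of the Bayesian indices literature) or over
#'   all draws.
#' @return list with `pct_in_rope` (percent) and `category`.
#' @export
rope_classify <- function(draws, rope_halfwidth = 0.1, hdi_prob = 0.89,
                          within_hdi = TRUE) {
  stopifnot(rope_halfwidth > 0)
  if (within_hdi) {
    h <- hdi(draws, hdi_prob)
    d <- draws[draws >= h[1L] & draws <= h[2L]]
  } else d <- draws
  pct <- 100 * mean(d >= -rope_halfwidth & d <= rope_halfwidth)
  category <- if (pct == 100) "null-accepted"
  else if (pct < 1) "significant"
  else if (pct < 2.5) "probably significant"
  else "undecided"
  list(pct_in_rope = pct, category = category)
}

# full index set for one parameter's draws
effect_summary_one <- function(draws, name, ci_level = 0.89,
                               rope_halfwidth = 0.1, hdi_prob = 0.89) {
  ps <- posterior_summary(draws, ci_level)
  h <- hdi(draws, hdi_prob)
  rc <- rope_classify(draws, rope_halfwidth, hdi_prob)
  data.frame(parameter = name, mean = ps$mean, lower = ps$lower, upper = ps$upper,
             pd = probability_of_direction(draws),
             hdi_lower = h[1L], hdi_upper = h[2L],
             pct_in_rope = rc$pct_in_rope, category = rc$category,
             stringsAsFactors = FALSE)
}

#' Effect indices for all covariate effects of a fitted model
#'
#' Posterior mean, credible interval, probability of direction, HDI and
#' ROPE coverage with significance category, for every species-level
#' climate/year slope on survival, the effort slope on recapture, and the
#' community trait slopes.
#'
#' @param fit a `cjs_fit`.
#' @param ci_level credible level of the equal-tailed interval.
#' @param rope_halfwidth ROPE half-width on the logit-scale slope.
#' @param hdi_prob HDI probability mass.
#' @return data frame with one row per effect: `species` (`NA` for
#'   community-level effects), `age`, `covariate`, and the index columns
#'   of `effect_summary_one`.
#' @export
effect_indices <- function(fit, ci_level = 0.89, rope_halfwidth = 0.1,
                           hdi_prob = 0.89) {
  map <- fit$map
  idx <- which(map$kind %in% c(3L, 5L))
  rows <- lapply(idx, function(i) {
    nm <- map$name[i]
    es <- effect_summary_one(fit$draws[, nm], nm, ci_level, rope_halfwidth, hdi_prob)
    age <- c("juv", "ad", "p")[map$age[i]]
    if (map$kind[i] == 3L) {
      cbind(data.frame(species = NA_character_, age = age,
                       covariate = c("MB", "BS")[map$t[i]]), es)
    } else {
      cov <- if (map$age[i] == 3L) "effort" else
        c("year", "temp", "precip", "enso")[map$t[i]]
      cbind(data.frame(species = fit$species[map$sp[i]], age = age,
                       covariate = cov), es)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
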