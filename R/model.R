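## Hierarchical two-age-class CJS model: parameters, linear predictors,
## priors, and the marginalized m-array multinomial likelihood.
##
## Species-level logit-linear regressions:
##   logit phi[t,s,juv] = alpha[s,juv] + b_year*year_t + b_temp*temp_t
##                        + b_precip*precip_t + b_enso*ENSO_t + eps[t,s,juv]
##   logit phi[t,s,ad]  = analogous with the adult coefficients
##   logit p[t,s]       = alpha[s,p] + b_effort*effort_t + eps[t,s,p]
## Community level: alpha[s,a] ~ Normal(mu_a + bMB_a*MB_s + bBS_a*BS_s,
## sigma_a); recapture intercepts alpha[s,p] ~ Normal(mu_p, sigma_p).
## Priors: inverse-logit of each mu ~ Uniform(0,1); every slope ~
## Normal(0, variance 10) (precision 0.1); hyper-SDs and temporal residual
## SDs ~ Uniform(0, 10).

SLOPE_SD <- sqrt(10)   # Normal prior SD for all regression slopes
SD_UPPER <- 10         # upper bound of the Uniform prior on all SDs

#' Construct an empty structured parameter set
#'
#' Allocates the full parameter structure of the hierarchical model for a
#' given problem size, filled with zeros (SDs with 1). Juvenile components
#' of species without juvenile releases are `NA` and are not model
#' parameters.
#'
#' @param species character vector of species codes.
#' @param has_juv logical vector: does each species have juvenile releases?
#' @param T number of occasions.
#' @return a list of class `cjs_params` with components `mu`, `sigma_mu`,
#'   `beta_trait`, `alpha`, `beta`, `sigma`, `eps`.
#' @export
cjs_params <- function(species, has_juv, T) {
  S <- length(species)
  vS <- setNames(numeric(S), species)
  mS <- function(r, rn) matrix(0, r, S, dimnames = list(rn, species))
  p <- list(
    mu = c(phi_juv = 0, phi_ad = 0, p = 0),
    sigma_mu = c(phi_juv = 1, phi_ad = 1, p = 1),
    beta_trait = list(juv = c(MB = 0, BS = 0), ad = c(MB = 0, BS = 0)),
    alpha = list(juv = vS, ad = vS, p = vS),
    beta = list(juv = mS(4, c("year", "temp", "precip", "enso")),
                ad = mS(4, c("year", "temp", "precip", "enso")),
                effort = vS),
    sigma = list(juv = vS + 1, ad = vS + 1, p = vS + 1),
    eps = list(juv = mS(T - 1, NULL), ad = mS(T - 1, NULL), p = mS(T - 1, NULL)))
  for (s in which(!has_juv)) {
    p$alpha$juv[s] <- NA; p$beta$juv[, s] <- NA
    p$sigma$juv[s] <- NA; p$eps$juv[, s] <- NA
  }
  attr(p, "has_juv") <- setNames(has_juv, species)
  class(p) <- "cjs_params"
  p
}

#' Evaluate the logit-linear predictors
#'
#' Maps model parameters and a covariate design to per-interval survival
#' and per-occasion recapture probabilities via the inverse-logit link.
#' Recapture probability is shared across age classes.
#'
#' @param params a `cjs_params` structure.
#' @param design a `cjs_design` (see [standardize_and_gate()]).
#' @param literal_intercepts if `TRUE`, the community hyper-means are used
#'   directly as regression intercepts instead of the species intercepts
#'   (the non-hierarchical literal regression form).
#' @return a list of class `rate_table`: matrices `phi_juv`, `phi_ad`
#'   ((T-1) x S, intervals x species) and `p` ((T-1) x S, rows = occasions
#'   2..T), all strictly inside (0, 1).
#' @export
linear_predictors <- function(params, design, literal_intercepts = FALSE) {
  iv <- design$intervals
  X <- rbind(year = iv$year_z, temp = iv$temp_z, precip = iv$precip_z, enso = iv$enso_z)
  if (any(!is.finite(X)) || any(!is.finite(design$effort_z)))
    stop("non-finite covariate in design", call. = FALSE)
  Tm1 <- ncol(X)
  sp <- names(params$alpha$ad)
  # survival: eta[t, s] = alpha_s + sum_k beta[k, s] * X[k, t] + eps[t, s]
  surv <- function(age) {
    a <- if (literal_intercepts) rep(params$mu[[paste0("phi_", age)]], length(sp))
         else params$alpha[[age]]
    eta <- outer(rep(1, Tm1), a) + crossprod(X, params$beta[[age]]) + params$eps[[age]]
    invlogit(eta)
  }
  phi_juv <- surv("juv"); phi_ad <- surv("ad")
  a_p <- if (literal_intercepts) rep(params$mu[["p"]], length(sp)) else params$alpha$p
  eff <- design$effort_z[-1L]                 # occasions 2..T
  eta_p <- outer(rep(1, Tm1), a_p) + outer(eff, params$beta$effort) + params$eps$p
  structure(list(phi_juv = phi_juv, phi_ad = phi_ad, p = invlogit(eta_p)),
            class = "rate_table")
}

#' Log-density of the hierarchical prior
#'
#' Sum of all log prior densities of a parameter set: logistic densities on
#' the logit-scale hyper-means (uniform on the probability scale, Jacobian
#' included), Normal(trait regression, hyper-SD) on species intercepts,
#' Normal(0, variance 10) on every slope, Normal(0, residual SD) on the
#' temporal residuals, and Uniform(0, 10) on all SDs. Returns `-Inf`
#' outside the support.
#'
#' @param params a `cjs_params` structure.
#' @param traits data frame with columns `species`, `MB`, `BS_z` (see
#'   [species_body_size()]), rows matching the species of `params`.
#' @param literal_intercepts if `TRUE`, species intercepts and trait slopes
#'   are not model parameters and contribute nothing.
#' @return scalar log prior density.
#' @export
hierarchical_logprior <- function(params, traits, literal_intercepts = FALSE) {
  has_juv <- attr(params, "has_juv")
  sds <- c(params$sigma_mu,
           params$sigma$juv[has_juv], params$sigma$ad, params$sigma$p)
  if (any(sds <= 0 | sds >= SD_UPPER)) return(-Inf)
  lp <- sum(dlogis(params$mu, log = TRUE)) + 3 * log(1 / SD_UPPER)
  lp <- lp + sum(dnorm(unlist(params$beta$juv[, has_juv, drop = FALSE]),
                       0, SLOPE_SD, log = TRUE)) +
    sum(dnorm(params$beta$ad, 0, SLOPE_SD, log = TRUE)) +
    sum(dnorm(params$beta$effort, 0, SLOPE_SD, log = TRUE))
  if (!literal_intercepts) {
    lp <- lp + sum(dnorm(unlist(params$beta_trait), 0, SLOPE_SD, log = TRUE))
    mu_juv_s <- params$mu[["phi_juv"]] +
      params$beta_trait$juv[["MB"]] * traits$MB + params$beta_trait$juv[["BS"]] * traits$BS_z
    mu_ad_s <- params$mu[["phi_ad"]] +
      params$beta_trait$ad[["MB"]] * traits$MB + params$beta_trait$ad[["BS"]] * traits$BS_z
    lp <- lp +
      sum(dnorm(params$alpha$juv[has_juv], mu_juv_s[has_juv],
                params$sigma_mu[["phi_juv"]], log = TRUE)) +
      sum(dnorm(params$alpha$ad, mu_ad_s, params$sigma_mu[["phi_ad"]], log = TRUE)) +
      sum(dnorm(params$alpha$p, params$mu[["p"]], params$sigma_mu[["p"]], log = TRUE))
  }
  # temporal residuals (SD recycled over the occasion dimension)
  for (age in c("juv", "ad", "p")) {
    keep <- if (age == "juv") has_juv else rep(TRUE, length(has_juv))
    e <- params$eps[[age]][, keep, drop = FALSE]
    s <- params$sigma[[age]][keep]
    lp <- lp + sum(dnorm(e, 0, rep(s, each = nrow(e)), log = TRUE))
  }
  lp
}

#' Cell probabilities of one m-array row set
#'
#' For releases of one age class of one species: the probability that a
#' bird released at occasion `i` is first re-encountered at occasion `j`
#' is first-interval survival (of the release age) times adult survival
#' and non-detection over intermediate intervals, times detection at `j`.
#'
#' @param phi_first length T-1 survival for the first interval after
#'   release (juvenile survival for juvenile releases).
#' @param phi_ad length T-1 adult survival per interval.
#' @param p length T-1 recapture probability at occasions 2..T.
#' @return (T-1) x T matrix: columns 1..T-1 are first-recapture occasions
#'   2..T, final column is the never-re-encountered probability. Rows sum
#'   to 1.
#' @export
marray_cell_probs <- function(phi_first, phi_ad, p) {
  Tm1 <- length(phi_first)
  stopifnot(length(phi_ad) == Tm1, length(p) == Tm1)
  cells <- matrix(0, Tm1, Tm1)
  for (i in seq_len(Tm1)) {
    surv <- phi_first[i]                      # alive at i+1
    for (j in i:Tm1) {                        # recapture occasion j+1
      if (j > i) surv <- surv * phi_ad[j] * (1 - p[j - 1L])
      cells[i, j] <- surv * p[j]
    }
  }
  cbind(cells, never = 1 - rowSums(cells))
}

#' Marginalized m-array multinomial log-likelihood
#'
#' The CJS likelihood with capture histories summarized as age-structured
#' m-arrays: each release row is multinomial over first-recapture occasion
#' (or never re-encountered). Equivalent to the individual state-space
#' formulation for models without individual covariates.
#'
#' @param marrays an `marray_set` (see [build_marrays()]).
#' @param rates a `rate_table` (see [linear_predictors()]) whose species
#'   columns match `names(marrays)`.
#' @param include_const include the multinomial coefficients (log
#'   factorials)? They are constants in the parameters; the sampler drops
#'   them.
#' @return scalar log-likelihood. Cell probabilities that underflow to 0
#'   or below are clamped at a log-floor and counted (attribute
#'   `n_clamped`).
#' @export
marray_loglik <- function(marrays, rates, include_const = TRUE) {
  sp <- names(marrays)
  n_clamped <- 0L
  ll <- 0
  for (k in seq_along(sp)) {
    s <- sp[k]
    for (age in c("juv", "ad")) {
      a <- marrays[[s]][[age]]
      if (sum(a$R) == 0L) next
      phi_first <- if (age == "juv") rates$phi_juv[, k] else rates$phi_ad[, k]
      pr <- marray_cell_probs(phi_first, rates$phi_ad[, k], rates$p[, k])
      cnt <- cbind(a$m, a$never)
      nz <- cnt > 0
      bad <- pr <= 0 & nz
      if (any(bad)) { n_clamped <- n_clamped + sum(bad); pr[pr <= 0] <- 1e-300 }
      ll <- ll + sum(cnt[nz] * log(pr[nz]))
      if (include_const)
        ll <- ll + sum(lgamma(a$R + 1)) - sum(lgamma(cnt + 1))
    }
  }
  if (n_clamped > 0L) cjs_log("marray_loglik: clamped %d underflowed cells", n_clamped)
  attr(ll, "n_clamped") <- n_clamped
  ll
}

#' Joint log-posterior of the hierarchical CJS model (reference path)
#'
#' Pure-R evaluation of prior + likelihood used as the reference against
#' which the compiled sampler's internal evaluation is cross-checked.
#' Multinomial constants are omitted.
#'
#' @param params a `cjs_params` structure.
#' @param marrays an `marray_set`.
#' @param design a `cjs_design`.
#' @param traits species trait data frame.
#' @param literal_intercepts see [linear_predictors()].
#' @return scalar log-posterior density (unnormalized).
#' @export
cjs_logpost <- function(params, marrays, design, traits, literal_intercepts = FALSE) {
  lp <- hierarchical_logprior(params, traits, literal_intercepts)
  if (!is.finite(lp)) return(-Inf)
  rates <- linear_predictors(params, design, literal_intercepts)
  lp + as.numeric(marray_loglik(marrays, rates, include_const = FALSE))
}
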