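## The user-facing model fit: assembles data for the compiled sampler,
## runs chains, diagnoses convergence, and wraps everything in a classed
## object with the usual methods.

#' Fit the multispecies hierarchical two-age-class CJS model
#'
#' Jointly estimates age-dependent apparent survival and recapture
#' probabilities for a community of species from age-structured m-arrays,
#' with community-level hyper-parameters, trait effects (migratory
#' behavior, standardized body size), species-level logit-linear climate
#' and year regressions on survival, an effort regression on recapture,
#' and year-level residual noise. Sampling is componentwise adaptive
#' random-walk Metropolis over the marginalized m-array multinomial
#' likelihood, run in compiled code with per-species likelihood caching.
#'
#' @param marrays an `marray_set` (see [build_marrays()]).
#' @param design a `cjs_design` (see [standardize_and_gate()]).
#' @param traits data frame with columns `species`, `MB` (1 = migrant),
#'   `BS_z` (standardized mean adult body mass), one row per species of
#'   `marrays`.
#' @param config MCMC configuration or profile name (see [mcmc_profile()]).
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param literal_intercepts fit the literal (non-hierarchical) regression
#'   form in which the community hyper-means are the regression intercepts.
#' @param min_juv_releases minimum number of juvenile first releases for a
#'   species to carry a juvenile age class (default 25, the study-design
#'   convention); below it the species' juvenile releases are excluded and
#'   only adult survival is estimated.
#' @param init_step initial proposal SD for the adaptive kernel.
#' @return an object of class `cjs_fit`.
#' @seealso [summary.cjs_fit()], [effect_indices()], [predict.cjs_fit()]
#' @export
fit_cjs_community <- function(marrays, design, traits, config = "test",
                              seed = 1L, literal_intercepts = FALSE,
                              min_juv_releases = 25L, init_step = 0.1) {
  t0 <- Sys.time()
  config <- mcmc_profile(config)
  species <- names(marrays)
  stopifnot(identical(sort(traits$species), species))
  traits <- traits[match(species, traits$species), , drop = FALSE]
  if (anyNA(traits$MB)) stop("missing migratory-behavior trait", call. = FALSE)
  n_juv_rel <- vapply(marrays, function(a) sum(a$juv$R), numeric(1))
  has_juv <- n_juv_rel >= min_juv_releases
  for (s in which(!has_juv & n_juv_rel > 0)) {
    cjs_log("%s: %d juvenile releases (< %d): juvenile class dropped",
            species[s], n_juv_rel[s], min_juv_releases)
    marrays[[s]]$juv$m[] <- 0L
    marrays[[s]]$juv$never[] <- 0L
    marrays[[s]]$juv$R[] <- 0L
    marrays[[s]]$has_juv <- FALSE
  }
  T <- length(attr(marrays, "years"))
  Tm1 <- T - 1L
  if (nrow(design$intervals) != Tm1)
    stop("design and m-arrays disagree on the number of occasions", call. = FALSE)
  map <- cjs_param_map(species, has_juv, T, literal_intercepts)
  iv <- design$intervals
  data <- list(
    S = length(species), T = T, has_juv = as.integer(has_juv),
    marrays = lapply(marrays, function(a) list(
      juv_m = a$juv$m * 1.0, juv_never = a$juv$never * 1.0, juv_R = a$juv$R * 1.0,
      ad_m = a$ad$m * 1.0, ad_never = a$ad$never * 1.0, ad_R = a$ad$R * 1.0)),
    X = rbind(iv$year_z, iv$temp_z, iv$precip_z, iv$enso_z),
    effort2 = design$effort_z[-1L],
    MB = as.numeric(traits$MB), BSz = as.numeric(traits$BS_z))

  init_theta <- function() {
    p <- cjs_params(species, has_juv, T)
    crude_p <- vapply(marrays, function(a) {
      R <- sum(a$juv$R) + sum(a$ad$R)
      nv <- sum(a$juv$never) + sum(a$ad$never)
      min(max((R - nv) / max(R, 1), 0.02), 0.9)
    }, numeric(1))
    p$mu <- c(phi_juv = logit(0.2), phi_ad = logit(0.4), p = mean(logit(crude_p))) +
      stats::rnorm(3, 0, 0.2)
    p$sigma_mu <- c(phi_juv = 0.7, phi_ad = 0.7, p = 0.7)
    p$alpha$juv <- ifelse(has_juv, logit(0.2) + stats::rnorm(length(species), 0, 0.3), NA)
    p$alpha$ad <- logit(0.4) + stats::rnorm(length(species), 0, 0.3)
    p$alpha$p <- logit(crude_p) + stats::rnorm(length(species), 0, 0.3)
    p$beta$juv[] <- ifelse(is.na(p$beta$juv), NA, stats::rnorm(length(p$beta$juv), 0, 0.1))
    p$beta$ad[] <- stats::rnorm(length(p$beta$ad), 0, 0.1)
    p$beta$effort <- stats::rnorm(length(species), 0, 0.1)
    p$sigma$juv <- ifelse(has_juv, 0.3, NA)
    p$sigma$ad[] <- 0.3; p$sigma$p[] <- 0.3
    params_to_vector(p, map)
  }

  n_kept_chain <- (config$iters - config$burnin) %/% config$thin
  draws <- matrix(NA_real_, n_kept_chain * config$chains, nrow(map),
                  dimnames = list(NULL, map$name))
  chain_id <- rep(seq_len(config$chains), each = n_kept_chain)
  accept <- matrix(NA_real_, config$chains, nrow(map))
  for (ch in seq_len(config$chains)) {
    set.seed(seed + ch - 1L)
    theta0 <- init_theta()
    res <- cjs_mcmc_cpp(theta0, data, map$kind, map$sp, map$t, map$age,
                        literal_intercepts, config$iters, config$burnin,
                        config$thin, init_step, 0.44)
    draws[chain_id == ch, ] <- res$draws
    accept[ch, ] <- res$accept
    cjs_log("chain %d done (mean acceptance %.2f)", ch, mean(res$accept))
  }
  rh <- vapply(seq_len(ncol(draws)), function(j)
    as.numeric(rhat(matrix(draws[, j], n_kept_chain, config$chains))),
    numeric(1))
  names(rh) <- map$name
  structure(list(draws = draws, chain = chain_id, map = map,
                 species = species, has_juv = has_juv, T = T,
                 years = attr(marrays, "years"),
                 marrays = marrays, design = design, traits = traits,
                 config = config, seed = seed,
                 literal_intercepts = literal_intercepts,
                 rhat = rh, accept = accept,
                 runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            class = "cjs_fit")
}

# posterior draws of the rate time-series for one species and one rate
# ("juv", "ad" survival over intervals; "p" recapture at occasions 2..T);
# with include_eps = FALSE the year-level residuals are set to zero
# (expected rates at the covariates, used for prediction on new designs)
rate_draws <- function(fit, species, rate = c("ad", "juv", "p"),
                       design = NULL, include_eps = TRUE) {
  rate <- match.arg(rate)
  design <- design %||% fit$design
  map <- fit$map
  s <- match(species, fit$species)
  if (rate == "juv" && !fit$has_juv[s]) return(NULL)
  iv <- design$intervals
  col <- function(name) fit$draws[, name]
  if (rate == "p") {
    a <- if (fit$literal_intercepts) col("mu_p") else col(sprintf("alpha_p[%s]", species))
    eta <- outer(a, rep(1, fit$T - 1)) +
      outer(col(sprintf("b_effort[%s]", species)), design$effort_z[-1L])
    if (include_eps)
      eta <- eta + fit$draws[, sprintf("eps_p[%d,%s]", seq_len(fit$T - 1), species)]
  } else {
    X <- rbind(iv$year_z, iv$temp_z, iv$precip_z, iv$enso_z)
    a <- if (fit$literal_intercepts) col(paste0("mu_phi_", rate))
         else col(sprintf("alpha_%s[%s]", rate, species))
    B <- fit$draws[, sprintf("b_%s_%s[%s]", c("year", "temp", "precip", "enso"),
                             rate, species)]
    eta <- outer(a, rep(1, fit$T - 1)) + B %*% X
    if (include_eps)
      eta <- eta + fit$draws[, sprintf("eps_%s[%d,%s]", rate, seq_len(fit$T - 1), species)]
  }
  invlogit(eta)
}

#' Species-level mean survival and recapture summaries
#'
#' Posterior summaries of each species' mean rate (the per-draw average of
#' the realized annual rates over the study's intervals), the quantities
#' reported in a study-level results table.
#'
#' @param fit a `cjs_fit`.
#' @param ci_level credible level(s) of the equal-tailed intervals
#'   (default both 0.89 and 0.95).
#' @return data frame: one row per species with posterior mean and CI
#'   bounds for juvenile survival (`NA` where the species has no juvenile
#'   class), adult survival and recapture probability.
#' @export
survival_summary <- function(fit, ci_level = c(0.89, 0.95)) {
  rows <- lapply(fit$species, function(sp) {
    out <- data.frame(species = sp)
    for (rate in c("juv", "ad", "p")) {
      d <- rate_draws(fit, sp, rate)
      nm <- c(juv = "phi_juv", ad = "phi_ad", p = "p")[[rate]]
      if (is.null(d)) {
        out[[paste0(nm, "_mean")]] <- NA_real_
        for (cl in ci_level) {
          out[[sprintf("%s_l%g", nm, 100 * cl)]] <- NA_real_
          out[[sprintf("%s_u%g", nm, 100 * cl)]] <- NA_real_
        }
      } else {
        m <- rowMeans(d)
        out[[paste0(nm, "_mean")]] <- mean(m)
        for (cl in ci_level) {
          q <- stats::quantile(m, c((1 - cl) / 2, 1 - (1 - cl) / 2), names = FALSE)
          out[[sprintf("%s_l%g", nm, 100 * cl)]] <- q[1L]
          out[[sprintf("%s_u%g", nm, 100 * cl)]] <- q[2L]
        }
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Individual-level capture/recapture counts per species and age class
#'
#' The C/R counts of a study summary table: unique individuals first
#' captured in each age class, and how many of them were re-encountered at
#' a later occasion.
#'
#' @param histories an `annual_histories` object.
#' @return data frame with columns `species`, `C_juv`, `R_juv`, `C_ad`,
#'   `R_ad`.
#' @export
history_counts <- function(histories) {
  n_det <- rowSums(histories$H)
  do.call(rbind, lapply(sort(unique(histories$species)), function(sp) {
    i <- histories$species == sp
    juv <- i & histories$age_at_first == "juvenile"
    ad <- i & histories$age_at_first == "adult"
    data.frame(species = sp,
               C_juv = sum(juv), R_juv = sum(n_det[juv] > 1L),
               C_ad = sum(ad), R_ad = sum(n_det[ad] > 1L))
  }))
}

#' @export
print.cjs_fit <- function(x, digits = 2, ...) {
  cat("Hierarchical two-age-class CJS community model\n")
  cat(sprintf("  %d species, %d occasions (%d-%d), %d parameters\n",
              length(x$species), x$T, min(x$years), max(x$years), ncol(x$draws)))
  cat(sprintf("  %d kept draws (%d chains x %d iterations, burn-in %d, thin %d)\n",
              nrow(x$draws), x$config$chains, x$config$iters,
              x$config$burnin, x$config$thin))
  head_rh <- x$rhat[x$map$kind <= 6]
  cat(sprintf("  max R-hat (structural parameters): %.3f%s\n",
              max(head_rh, na.rm = TRUE),
              if (any(head_rh >= 1.1, na.rm = TRUE)) "  [NOT CONVERGED]" else ""))
  s <- survival_summary(x, ci_level = 0.89)
  cat("\nPosterior mean rates (89% CI):\n")
  fmt <- function(m, l, u) ifelse(is.na(m), "", sprintf("%.*f (%.*f, %.*f)",
                                                        digits, m, digits, l, digits, u))
  tab <- data.frame(species = s$species,
                    phi_juv = fmt(s$phi_juv_mean, s$phi_juv_l89, s$phi_juv_u89),
                    phi_ad = fmt(s$phi_ad_mean, s$phi_ad_l89, s$phi_ad_u89),
                    p = fmt(s$p_mean, s$p_l89, s$p_u89))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Summarize a fitted community CJS model
#'
#' @param object a `cjs_fit`.
#' @param ci_level credible level for parameter intervals.
#' @param ... unused.
#' @return list of class `summary.cjs_fit` with `params` (per-parameter
#'   posterior mean, CI, R-hat), `survival` (species-level rate table) and
#'   `unconverged` (parameter names with R-hat >= 1.1).
#' @export
summary.cjs_fit <- function(object, ci_level = 0.89, ...) {
  ps <- posterior_summary(object$draws, ci_level)
  ps$rhat <- object$rhat
  structure(list(params = ps,
                 survival = survival_summary(object),
                 unconverged = names(object$rhat)[!is.na(object$rhat) &
                                                    object$rhat >= 1.1],
                 ci_level = ci_level),
            class = "summary.cjs_fit")
}

#' @export
print.summary.cjs_fit <- function(x, ...) {
  cat(sprintf("Parameter summaries (posterior mean, %g%% CI, R-hat):\n",
              100 * x$ci_level))
  print(utils::head(round(x$params, 3), 20))
  if (nrow(x$params) > 20) cat("  ... (", nrow(x$params), "parameters )\n")
  if (length(x$unconverged))
    cat("Unconverged parameters (R-hat >= 1.1):",
        paste(utils::head(x$unconverged, 10), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.cjs_fit <- function(object, ...) colMeans(object$draws)

#' Posterior predicted survival and recapture rates
#'
#' @param object a `cjs_fit`.
#' @param design optional `cjs_design` with new covariates; year-level
#'   residuals are then set to zero (expected rates). Defaults to the
#'   fitted design with residuals included.
#' @param ci_level credible level.
#' @param ... unused.
#' @return data frame with one row per species x rate x interval:
#'   posterior `mean`, `lower`, `upper`.
#' @export
predict.cjs_fit <- function(object, design = NULL, ci_level = 0.89, ...) {
  include_eps <- is.null(design)
  out <- list()
  for (sp in object$species) {
    for (rate in c("juv", "ad", "p")) {
      d <- rate_draws(object, sp, rate, design = design, include_eps = include_eps)
      if (is.null(d)) next
      ps <- posterior_summary(d, ci_level)
      occ <- if (rate == "p") object$years[-1L] else object$years[-object$T]
      out[[length(out) + 1L]] <- data.frame(
        species = sp, rate = c(juv = "phi_juv", ad = "phi_ad", p = "p")[[rate]],
        occasion = occ, ps)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Plot a fitted community CJS model
#'
#' `type = "survival"` draws per-species posterior mean annual survival
#' with credible bands; `type = "trace"` draws traceplots of the
#' community hyper-means.
#'
#' @param x a `cjs_fit`.
#' @param type `"survival"` or `"trace"`.
#' @param ... passed to the underlying plotting functions.
#' @return invisibly, `x`.
#' @export
plot.cjs_fit <- function(x, type = c("survival", "trace"), ...) {
  type <- match.arg(type)
  if (type == "survival") {
    pr <- predict(x)
    pr <- pr[pr$rate == "phi_ad", ]
    sp <- unique(pr$species)
    op <- graphics::par(mfrow = c(ceiling(length(sp) / 2), 2), mar = c(3, 3, 2, 1))
    on.exit(graphics::par(op))
    for (s in sp) {
      d <- pr[pr$species == s, ]
      graphics::plot(d$occasion, d$mean, type = "l", ylim = c(0, 1),
                     xlab = "", ylab = "adult survival", main = s, ...)
      graphics::polygon(c(d$occasion, rev(d$occasion)), c(d$lower, rev(d$upper)),
                        col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
      graphics::lines(d$occasion, d$mean, lwd = 2)
    }
  } else {
    pars <- intersect(c("mu_phi_juv", "mu_phi_ad", "mu_p"), colnames(x$draws))
    op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
    on.exit(graphics::par(op))
    for (p in pars) {
      graphics::plot(x$draws[, p], type = "n", ylab = p, xlab = "")
      for (ch in unique(x$chain))
        graphics::lines(which(x$chain == ch) - min(which(x$chain == ch)) + 1,
                        x$draws[x$chain == ch, p], col = ch)
    }
  }
  invisible(x)
}
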