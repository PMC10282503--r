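## Synthetic-study generator: builds complete banding-record, weather,
## ENSO, effort and trait tables from known parameters with exactly the
## statistical structure the analysis assumes, plus a ground-truth sidecar
## (true parameters, true rates, true m-arrays) so every downstream stage
## has an oracle.

# fixed-calendar day-of-year (Feb 29 mapped onto Feb 28) so that the
# seasonal temperature cycle is identical across years and a noiseless
# linear trend aggregates to an exactly linear winter series
doy_fixed <- function(month, day) {
  cum <- c(0L, cumsum(c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L)))
  cum[month] + pmin(day, c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month])
}

#' Define a synthetic study scenario
#'
#' The defaults describe a 20-occasion, five-species sub-Antarctic forest
#' passerine study: species sample sizes, true survival/recapture levels
#' and the single migrant species carrying nonzero precipitation and ENSO
#' effects on juvenile survival match the magnitudes of the motivating
#' study design; the weather generator plants a 0.10 degree C per year
#' trend in winter minimum temperature. Species without a juvenile
#' schedule are modeled as adult-only.
#'
#' @param T number of annual occasions.
#' @param start_year label of the first breeding season.
#' @param species data frame with columns `name`, `n_juv`, `n_ad` (total
#'   newly banded individuals per age class over the study), `phi_juv`,
#'   `phi_ad`, `p` (true mean rates; `phi_juv` `NA` for adult-only
#'   species), `MB` (1 = migrant), `BS` (mean adult mass, g).
#' @param beta named list of true logit-scale slopes per species; see the
#'   default for the structure (matrices covariate x species).
#' @param sigma_res true year-level residual SDs (juvenile survival,
#'   adult survival, recapture).
#' @param env weather/ENSO/effort generation parameters.
#' @param unknown_age_frac fraction of adult first captures recoded to
#'   age `"unknown"` (the analysis treats unknowns as adults).
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(T = 20L, start_year = 2001L,
                         species = NULL, beta = NULL,
                         sigma_res = c(juv = 0.3, ad = 0.3, p = 0.3),
                         env = list(), unknown_age_frac = 0.1) {
  if (is.null(species)) {
    species <- data.frame(
      name = c("rayadito", "elaenia", "house_wren", "thrush", "sierra_finch"),
      n_juv = c(323L, 375L, 0L, 0L, 772L),
      n_ad = c(474L, 676L, 136L, 73L, 780L),
      phi_juv = c(0.28, 0.24, NA, NA, 0.13),
      phi_ad = c(0.40, 0.60, 0.52, 0.45, 0.34),
      p = c(0.40, 0.11, 0.05, 0.19, 0.16),
      MB = c(0L, 1L, 0L, 0L, 0L),
      BS = c(11, 16, 12, 95, 22),
      stringsAsFactors = FALSE)
  }
  S <- nrow(species)
  if (is.null(beta)) {
    z <- matrix(0, 4, S, dimnames = list(c("year", "temp", "precip", "enso"),
                                         species$name))
    bj <- z
    if ("elaenia" %in% species$name) {
      bj["precip", "elaenia"] <- 1.45
      bj["enso", "elaenia"] <- -1.60
    }
    beta <- list(juv = bj, ad = z,
                 effort = setNames(rep(0.3, S), species$name))
  }
  env <- utils::modifyList(list(
    tmin_annual_mean = 5, tmin_seasonal_amp = 4.5, tmin_trend = 0.10,
    tmin_noise_sd = 2.0, precip_meanlog = -0.3, precip_sdlog = 1.2,
    mei_rho = 0.85, mei_sd = 0.3, effort_base = 1500, effort_sdlog = 0.3), env)
  structure(list(T = as.integer(T), start_year = as.integer(start_year),
                 species = species, beta = beta, sigma_res = sigma_res,
                 env = env, unknown_age_frac = unknown_age_frac),
            class = "sim_scenario")
}

#' Simulate daily weather, monthly ENSO and annual effort tables
#'
#' Daily minimum temperature = annual mean + seasonal cosine (warmest
#' mid-January, coldest mid-July) + linear trend + Gaussian noise; daily
#' precipitation is log-normal; the monthly ENSO index is a stationary
#' AR(1); annual effort is log-normal around a base level. Deterministic
#' given the seed.
#'
#' @param scenario a `sim_scenario`.
#' @param seed integer seed.
#' @return list with data frames `weather` (`date`, `tmin_c`,
#'   `precip_mm`), `mei` (`year`, `month`, `mei`) and `effort`
#'   (`occasion_year`, `net_hours_area`).
#' @export
simulate_environment <- function(scenario, seed = 1L) {
  set.seed(seed)
  e <- scenario$env
  y0 <- scenario$start_year
  dates <- seq(as.Date(sprintf("%d-01-01", y0)),
               as.Date(sprintf("%d-12-31", y0 + scenario$T - 1L)), by = "day")
  mth <- as.integer(format(dates, "%m")); dy <- as.integer(format(dates, "%d"))
  yr <- as.integer(format(dates, "%Y"))
  doy <- doy_fixed(mth, dy)
  tmin <- e$tmin_annual_mean +
    e$tmin_seasonal_amp * cos(2 * pi * (doy - 15) / 365) +
    e$tmin_trend * (yr - y0) +
    stats::rnorm(length(dates), 0, e$tmin_noise_sd)
  precip <- stats::rlnorm(length(dates), e$precip_meanlog, e$precip_sdlog)
  weather <- data.frame(date = dates, tmin_c = tmin, precip_mm = precip)
  n_m <- 12L * (scenario$T + 1L)
  mei_v <- numeric(n_m)
  innov_sd <- e$mei_sd
  mei_v[1L] <- stats::rnorm(1L, 0, innov_sd / sqrt(1 - e$mei_rho^2))
  for (i in 2:n_m) mei_v[i] <- e$mei_rho * mei_v[i - 1L] + stats::rnorm(1L, 0, innov_sd)
  mei <- data.frame(year = rep(y0:(y0 + scenario$T), each = 12L),
                    month = rep(1:12, scenario$T + 1L), mei = mei_v)
  effort <- data.frame(occasion_year = y0:(y0 + scenario$T - 1L),
                       net_hours_area = e$effort_base *
                         exp(stats::rnorm(scenario$T, 0, e$effort_sdlog)))
  list(weather = weather, mei = mei, effort = effort)
}

# covariate design implied by a simulated (or real) environment
design_from_environment <- function(env_tables, years) {
  w <- aggregate_weather(env_tables$weather, years)
  en <- aggregate_enso(env_tables$mei, years)
  standardize_and_gate(w, en, env_tables$effort, years)
}

# true structured parameters of a scenario (species intercepts at the
# logit of the stated mean rates; hyper-parameters recorded as their
# across-species summaries)
true_params <- function(scenario, design, seed = 1L) {
  sp <- scenario$species
  has_juv <- sp$n_juv > 0L
  p <- cjs_params(sp$name, has_juv, scenario$T)
  p$alpha$juv <- ifelse(has_juv, logit(sp$phi_juv), NA)
  p$alpha$ad <- logit(sp$phi_ad)
  p$alpha$p <- logit(sp$p)
  p$mu <- c(phi_juv = mean(p$alpha$juv[has_juv]), phi_ad = mean(p$alpha$ad),
            p = mean(p$alpha$p))
  sd0 <- function(x) if (length(x) > 1L) max(sd(x), 0.3) else 0.3
  p$sigma_mu <- c(phi_juv = sd0(p$alpha$juv[has_juv]),
                  phi_ad = sd0(p$alpha$ad), p = sd0(p$alpha$p))
  p$beta$juv[] <- ifelse(is.na(p$beta$juv), NA, scenario$beta$juv)
  p$beta$ad[] <- scenario$beta$ad
  p$beta$effort[] <- scenario$beta$effort
  p$sigma$juv <- ifelse(has_juv, scenario$sigma_res[["juv"]], NA)
  p$sigma$ad[] <- scenario$sigma_res[["ad"]]
  p$sigma$p[] <- scenario$sigma_res[["p"]]
  set.seed(seed)
  Tm1 <- scenario$T - 1L
  for (s in seq_len(nrow(sp))) {
    if (has_juv[s]) p$eps$juv[, s] <- stats::rnorm(Tm1, 0, p$sigma$juv[s])
    p$eps$ad[, s] <- stats::rnorm(Tm1, 0, p$sigma$ad[s])
    p$eps$p[, s] <- stats::rnorm(Tm1, 0, p$sigma$p[s])
  }
  p
}

# deterministic near-uniform allocation of n new releases over T occasions
release_schedule <- function(n, T) {
  base <- n %/% T
  extra <- n %% T
  base + c(rep(1L, extra), rep(0L, T - extra))
}

#' Simulate banding records from a scenario
#'
#' Draws true annual rates from the scenario's parameters and the
#' simulated environment, simulates every released individual forward
#' (juveniles age into adults after one interval), and emits dated
#' breeding-season banding records, one to three handling events per
#' detected season. A configurable fraction of adult first captures is
#' recoded to age `"unknown"`. Ground truth (true parameters, rates,
#' histories and m-arrays) is returned alongside.
#'
#' @param scenario a `sim_scenario`.
#' @param env_tables output of [simulate_environment()].
#' @param seed integer seed.
#' @param emit_records also emit dated banding records (set `FALSE` when
#'   only the truth histories/m-arrays are needed, e.g. in simulation
#'   studies that start from m-arrays).
#' @return list with `records` (banding data frame, `NULL` if not
#'   emitted), `traits` (species, MB), and `truth` (list: `params`,
#'   `rates`, `design`, `histories`, `marrays`).
#' @export
simulate_histories <- function(scenario, env_tables, seed = 1L,
                               emit_records = TRUE) {
  T <- scenario$T
  years <- scenario$start_year:(scenario$start_year + T - 1L)
  design <- design_from_environment(env_tables, years)
  params <- true_params(scenario, design, seed = seed + 1L)
  rates <- linear_predictors(params, design)
  sp <- scenario$species
  set.seed(seed + 2L)
  n_total <- sum(sp$n_juv) + sum(sp$n_ad)
  H <- matrix(0L, n_total, T)
  species_i <- character(n_total); age_i <- character(n_total)
  first_i <- integer(n_total)
  i <- 0L
  for (s in seq_len(nrow(sp))) {
    sched <- cbind(juv = release_schedule(sp$n_juv[s], T),
                   ad = release_schedule(sp$n_ad[s], T))
    for (f in seq_len(T)) for (age0 in c("juv", "ad")) {
      for (b in seq_len(sched[f, age0])) {
        i <- i + 1L
        H[i, f] <- 1L
        if (f < T) for (t in f:(T - 1L)) {
          phi <- if (age0 == "juv" && t == f) rates$phi_juv[t, s] else rates$phi_ad[t, s]
          if (stats::runif(1L) > phi) break
          if (stats::runif(1L) < rates$p[t, s]) H[i, t + 1L] <- 1L
        }
        species_i[i] <- sp$name[s]
        age_i[i] <- if (age0 == "juv") "juvenile" else "adult"
        first_i[i] <- f
      }
    }
  }
  ids <- sprintf("B%06d", seq_len(n_total))
  rownames(H) <- ids
  truth_hist <- structure(list(H = H, species = species_i, age_at_first = age_i,
                               first = first_i, years = years),
                          class = "annual_histories")
  records <- NULL
  if (emit_records) {
    season_months <- c(9:12, 1:3)
    det_idx <- which(H == 1L, arr.ind = TRUE)
    n_ev <- 1L + stats::rbinom(nrow(det_idx), 2L, 0.2)
    unknown_first <- stats::runif(n_total) < scenario$unknown_age_frac
    ri <- rep(det_idx[, 1L], n_ev)           # individual per event
    ro <- rep(det_idx[, 2L], n_ev)           # occasion per event
    mo <- sample(season_months, length(ri), replace = TRUE)
    dd <- sample(1:28, length(ri), replace = TRUE)
    yy <- ifelse(mo >= 9L, years[ro], years[ro] + 1L)
    is_first <- ro == first_i[ri]
    code <- ifelse(is_first & age_i[ri] == "juvenile", "juvenile",
                   ifelse(is_first & unknown_first[ri], "unknown", "adult"))
    bs <- sp$BS[match(species_i[ri], sp$name)]
    mass <- round(ifelse(code == "juvenile",
                         stats::rnorm(length(ri), 0.9 * bs, 0.07 * bs),
                         stats::rnorm(length(ri), bs, 0.05 * bs)), 1)
    records <- data.frame(band_id = ids[ri], species = species_i[ri],
                          date = sprintf("%d-%02d-%02d", yy, mo, dd),
                          age_code = code, body_mass = mass,
                          stringsAsFactors = FALSE)
    records <- records[order(records$date, records$band_id), ]
    rownames(records) <- NULL
  }
  list(records = records,
       traits = data.frame(species = sp$name, MB = sp$MB,
                           stringsAsFactors = FALSE),
       truth = list(params = params, rates = rates, design = design,
                    histories = truth_hist,
                    marrays = build_marrays(truth_hist)))
}

#' Simulate a complete study and write its input files
#'
#' Runs [simulate_environment()] and [simulate_histories()] and writes the
#' CSV dialects the ingestion functions read (`banding.csv`,
#' `weather.csv`, `mei.csv`, `effort.csv`, `traits.csv`), plus a
#' `truth/` sidecar directory with the true parameters (JSON), true rates
#' (CSV) and true m-arrays.
#'
#' @param scenario a `sim_scenario`.
#' @param dir output directory.
#' @param seed integer master seed (table-specific seeds are derived from
#'   it).
#' @return invisibly, the in-memory simulation (environment tables plus
#'   the [simulate_histories()] output).
#' @export
simulate_study <- function(scenario, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  env_tables <- simulate_environment(scenario, seed = seed)
  sim <- simulate_histories(scenario, env_tables, seed = seed + 1000L)
  utils::write.csv(sim$records, file.path(dir, "banding.csv"), row.names = FALSE)
  utils::write.csv(env_tables$weather, file.path(dir, "weather.csv"), row.names = FALSE)
  utils::write.csv(env_tables$mei, file.path(dir, "mei.csv"), row.names = FALSE)
  utils::write.csv(env_tables$effort, file.path(dir, "effort.csv"), row.names = FALSE)
  utils::write.csv(sim$traits, file.path(dir, "traits.csv"), row.names = FALSE)
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  write_marrays(sim$truth$marrays, file.path(tdir, "marrays"))
  rates <- sim$truth$rates
  utils::write.csv(
    data.frame(interval = seq_len(scenario$T - 1L),
               setNames(as.data.frame(rates$phi_juv), paste0("phi_juv.", scenario$species$name)),
               setNames(as.data.frame(rates$phi_ad), paste0("phi_ad.", scenario$species$name)),
               setNames(as.data.frame(rates$p), paste0("p.", scenario$species$name))),
    file.path(tdir, "true_rates.csv"), row.names = FALSE)
  map <- cjs_param_map(scenario$species$name, scenario$species$n_juv > 0L, scenario$T)
  jsonlite::write_json(as.list(params_to_vector(sim$truth$params, map)),
                       file.path(tdir, "true_params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(env_tables, sim))
}
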