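## End-to-end orchestration: prepare (ingest + covariates) -> GOF -> fit
## -> effect indices -> reports. Every intermediate artifact is plain
## CSV/JSON so each stage is independently re-runnable and testable.

#' Build a pipeline configuration
#'
#' @param banding,weather,mei,effort,traits input CSV paths (see the
#'   ingestion functions for the expected columns; `traits` needs
#'   `species`, `MB`). Alternatively supply `scenario` to simulate the
#'   inputs in-memory.
#' @param scenario optional `sim_scenario` replacing the file inputs.
#' @param season breeding-season months, starting month first.
#' @param years optional occasion-year labels (default: observed range).
#' @param min_captures,min_recaptures species-inclusion thresholds.
#' @param mcmc_profile `"test"` or `"full"` (see [mcmc_profile()]).
#' @param ci_levels credible levels reported in the rate table.
#' @param rope ROPE half-width for effect categories.
#' @param seed integer seed for simulation and MCMC.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param file optional YAML file; fields read from it are overridden by
#'   any argument supplied explicitly.
#' @return a named configuration list of class `run_config`.
#' @export
pipeline_config <- function(banding = NULL, weather = NULL, mei = NULL,
                            effort = NULL, traits = NULL, scenario = NULL,
                            season = c(9:12, 1:3), years = NULL,
                            min_captures = 50, min_recaptures = 4,
                            mcmc_profile = "test", ci_levels = c(0.89, 0.95),
                            rope = 0.1, seed = 1L, out_dir = NULL,
                            file = NULL) {
  cfg <- as.list(environment())
  cfg$file <- NULL
  if (!is.null(file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed to read config files", call. = FALSE)
    from_file <- yaml::read_yaml(file)
    supplied <- names(as.list(match.call()))[-1L]
    for (nm in setdiff(names(from_file), supplied)) cfg[[nm]] <- from_file[[nm]]
  }
  for (nm in c("banding", "weather", "mei", "effort", "traits")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop("input file not found: ", cfg[[nm]], call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full survival analysis pipeline
#'
#' Ingests (or simulates) banding and environmental data, builds annual
#' capture histories and the covariate design, runs the goodness-of-fit
#' suite, fits the hierarchical community CJS model, computes effect
#' indices and covariate trend tests, and writes publication-style
#' outputs: a species rate table, an effect-index table, GOF and trend
#' reports, and a machine-readable run manifest.
#'
#' @param config a `run_config` (see [pipeline_config()]).
#' @return invisibly, a result bundle: list with `histories`, `counts`,
#'   `marrays`, `design`, `traits`, `gof`, `trends`, `fit`, `effects`,
#'   `rate_table`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- as.integer(config$seed)
  if (!is.null(config$scenario)) {
    cjs_log("simulating study inputs (seed %d)", seed)
    env_tables <- simulate_environment(config$scenario, seed = seed)
    sim <- simulate_histories(config$scenario, env_tables, seed = seed + 1000L)
    records <- sim$records
    mb_tab <- sim$traits
  } else {
    records <- read_captures(config$banding)
    env_tables <- list(weather = utils::read.csv(config$weather),
                       mei = utils::read.csv(config$mei),
                       effort = utils::read.csv(config$effort))
    mb_tab <- utils::read.csv(config$traits)
  }
  records$date <- as.Date(records$date)
  histories <- collapse_to_annual(records, season = config$season,
                                  years = config$years)
  cjs_log("collapsed %d records to %d individuals x %d occasions",
          nrow(records), nrow(histories$H), length(histories$years))
  retained <- filter_species(histories, config$min_captures, config$min_recaptures)
  if (length(retained) == 0L) stop("no species passes the inclusion filter", call. = FALSE)
  histories <- subset_species(histories, retained)
  counts <- history_counts(histories)
  marrays <- build_marrays(histories)
  design <- design_from_environment(env_tables, histories$years)
  trends <- climate_trends(design)
  gof <- cjs_gof(histories)
  bs <- species_body_size(records, species = retained)
  traits <- data.frame(species = bs$species,
                       MB = mb_tab$MB[match(bs$species, mb_tab$species)],
                       BS = bs$BS, BS_z = bs$BS_z)
  fit <- fit_cjs_community(marrays, design, traits,
                           config = config$mcmc_profile, seed = seed)
  effects <- effect_indices(fit, rope_halfwidth = config$rope)
  rate_table <- report_tables(fit, counts, ci_levels = config$ci_levels)
  head_idx <- fit$map$kind <= 6
  unconv <- names(fit$rhat)[head_idx & !is.na(fit$rhat) & fit$rhat >= 1.1]
  manifest <- list(
    seed = seed, package_version = as.character(utils::packageVersion("cjscommunity")),
    n_records = nrow(records), n_individuals = nrow(histories$H),
    species = retained, occasions = histories$years,
    mcmc = fit$config, kept_draws = nrow(fit$draws),
    max_rhat_structural = max(fit$rhat[head_idx], na.rm = TRUE),
    unconverged = unconv)
  if (length(unconv))
    warning("unconverged structural parameters: ",
            paste(utils::head(unconv, 5), collapse = ", "), call. = FALSE)
  bundle <- list(histories = histories, counts = counts, marrays = marrays,
                 design = design, traits = traits, gof = gof, trends = trends,
                 fit = fit, effects = effects, rate_table = rate_table,
                 manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(bundle, config$out_dir)
  invisible(bundle)
}

write_pipeline_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$rate_table, file.path(out_dir, "rate_table.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$effects, file.path(out_dir, "effects.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$gof, file.path(out_dir, "gof.csv"), row.names = FALSE)
  utils::write.csv(bundle$trends, file.path(out_dir, "trends.csv"), row.names = FALSE)
  iv <- bundle$design$intervals
  utils::write.csv(iv, file.path(out_dir, "covariates.csv"), row.names = FALSE)
  write_marrays(bundle$marrays, file.path(out_dir, "marrays"))
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Format the species rate table
#'
#' Builds the study-style results table: per species, formatted
#' `"mean (lower, upper)"` strings for juvenile survival, adult survival
#' and recapture probability (blank where a species has no juvenile
#' class), and `C/R` capture/recapture count columns per age class.
#'
#' @param fit a `cjs_fit`.
#' @param counts output of [history_counts()].
#' @param ci_levels credible levels to include (a formatted column per
#'   level; numeric columns use the first level).
#' @param digits decimals in the formatted strings.
#' @return data frame, one row per species.
#' @export
report_tables <- function(fit, counts, ci_levels = c(0.89, 0.95), digits = 2) {
  s <- survival_summary(fit, ci_level = ci_levels)
  fmt <- function(m, l, u) ifelse(is.na(m), "",
                                  sprintf("%.*f (%.*f, %.*f)", digits, m,
                                          digits, l, digits, u))
  out <- data.frame(species = s$species)
  for (rate in c("phi_juv", "phi_ad", "p")) {
    out[[paste0(rate, "_mean")]] <- round(s[[paste0(rate, "_mean")]], digits)
    for (cl in ci_levels) {
      lab <- sprintf("%s_ci%g", rate, 100 * cl)
      out[[lab]] <- fmt(s[[paste0(rate, "_mean")]],
                        s[[sprintf("%s_l%g", rate, 100 * cl)]],
                        s[[sprintf("%s_u%g", rate, 100 * cl)]])
    }
  }
  cr <- counts[match(out$species, counts$species), ]
  out$CR_juv <- ifelse(cr$C_juv > 0, paste0(cr$C_juv, "/", cr$R_juv), "")
  out$CR_ad <- paste0(cr$C_ad, "/", cr$R_ad)
  out
}
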