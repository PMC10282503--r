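# one shared small fit for the method tests (kept cheap: tiny chains)
fit_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- sim_scenario()
    env <- simulate_environment(sc, 7)
    sim <- simulate_histories(sc, env, 7, emit_records = FALSE)
    fit <- fit_cjs_community(sim$truth$marrays, sim$truth$design,
                             scenario_traits(sc),
                             config = list(chains = 2L, iters = 800L,
                                           burnin = 300L, thin = 1L),
                             seed = 3)
    cache <<- list(fit = fit, sim = sim, sc = sc)
    cache
  }
})

test_that("the compiled log-posterior agrees with the pure-R reference", {
  sc <- sim_scenario()
  env <- simulate_environment(sc, 7)
  sim <- simulate_histories(sc, env, 7, emit_records = FALSE)
  ma <- sim$truth$marrays; des <- sim$truth$design
  tr <- scenario_traits(sc)
  species <- names(ma)
  has_juv <- vapply(ma, function(a) sum(a$juv$R) > 0, logical(1))
  map <- cjs_param_map(species, has_juv, sc$T)
  iv <- des$intervals
  data <- list(S = length(species), T = sc$T, has_juv = as.integer(has_juv),
               marrays = lapply(ma, function(a) list(
                 juv_m = a$juv$m * 1.0, juv_never = a$juv$never * 1.0,
                 juv_R = a$juv$R * 1.0, ad_m = a$ad$m * 1.0,
                 ad_never = a$ad$never * 1.0, ad_R = a$ad$R * 1.0)),
               X = rbind(iv$year_z, iv$temp_z, iv$precip_z, iv$enso_z),
               effort2 = des$effort_z[-1],
               MB = as.numeric(tr$MB), BSz = as.numeric(tr$BS_z))
  set.seed(31)
  for (r in 1:5) {
    th <- rnorm(nrow(map), 0, 0.6)
    th[map$kind %in% c(2L, 6L)] <- runif(sum(map$kind %in% c(2L, 6L)), 0.1, 2)
    pp <- vector_to_params(th, map, species, has_juv, sc$T)
    expect_equal(cjscommunity:::cjs_logpost_cpp(th, data, map$kind, map$sp,
                                                map$t, map$age, FALSE),
                 cjs_logpost(pp, ma, des, tr), tolerance = 1e-9)
  }
  # round trip through the flat layout is lossless
  th <- rnorm(nrow(map), 0, 0.4)
  th[map$kind %in% c(2L, 6L)] <- 1
  pp <- vector_to_params(th, map, species, has_juv, sc$T)
  expect_equal(unname(params_to_vector(pp, map)), th)
})

test_that("a fitted model has coherent structure and methods", {
  fx <- fit_fixture()
  fit <- fx$fit
  expect_s3_class(fit, "cjs_fit")
  expect_equal(nrow(fit$draws), kept_draws(fit$config))
  expect_equal(ncol(fit$draws), nrow(fit$map))
  expect_false(anyNA(fit$draws))
  expect_true(all(is.finite(fit$rhat) | is.na(fit$rhat)))

  expect_output(print(fit), "Hierarchical two-age-class")
  s <- summary(fit)
  expect_s3_class(s, "summary.cjs_fit")
  expect_equal(nrow(s$params), ncol(fit$draws))
  cf <- coef(fit)
  expect_equal(length(cf), ncol(fit$draws))
  expect_equal(unname(cf), unname(colMeans(fit$draws)))

  pr <- predict(fit)
  expect_true(all(pr$mean > 0 & pr$mean < 1))
  expect_true(all(pr$lower <= pr$mean & pr$mean <= pr$upper))
  # species without juveniles contribute no juvenile rows
  expect_false(any(pr$species == "house_wren" & pr$rate == "phi_juv"))

  ss <- survival_summary(fit)
  expect_true(all(is.na(ss$phi_juv_mean) | (ss$phi_juv_mean > 0 & ss$phi_juv_mean < 1)))
  expect_true(all(ss$phi_ad_mean > 0 & ss$phi_ad_mean < 1))
  expect_equal(ss$species, sort(fx$sc$species$name))

  ef <- effect_indices(fit)
  expect_true(all(ef$pd >= 50 & ef$pd <= 100))
  expect_true(all(ef$pct_in_rope >= 0 & ef$pct_in_rope <= 100))
  expect_true(all(ef$category %in%
                    c("significant", "probably significant",
                      "undecided", "null-accepted")))
  # juvenile slopes exist only for species with a juvenile class
  expect_false(any(ef$species == "thrush" & ef$age == "juv", na.rm = TRUE))

  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); plot(fit, type = "trace"); grDevices::dev.off()
  expect_true(file.exists(f))
  unlink(f)
})

test_that("fits are bit-identical under the same seed and differ otherwise", {
  sc <- sim_scenario()
  env <- simulate_environment(sc, 7)
  sim <- simulate_histories(sc, env, 7, emit_records = FALSE)
  cfg <- list(chains = 2L, iters = 400L, burnin = 100L, thin = 1L)
  tr <- scenario_traits(sc)
  f1 <- fit_cjs_community(sim$truth$marrays, sim$truth$design, tr, cfg, seed = 5)
  f2 <- fit_cjs_community(sim$truth$marrays, sim$truth$design, tr, cfg, seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_cjs_community(sim$truth$marrays, sim$truth$design, tr, cfg, seed = 6)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the literal regression form drops the hierarchy", {
  sc <- sim_scenario()
  env <- simulate_environment(sc, 7)
  sim <- simulate_histories(sc, env, 7, emit_records = FALSE)
  fit <- fit_cjs_community(sim$truth$marrays, sim$truth$design,
                           scenario_traits(sc),
                           config = list(chains = 2L, iters = 300L,
                                         burnin = 100L, thin = 1L),
                           seed = 2, literal_intercepts = TRUE)
  expect_false(any(fit$map$kind %in% c(2L, 3L, 4L)))
  expect_true(all(c("mu_phi_juv", "mu_phi_ad", "mu_p") %in% colnames(fit$draws)))
})

test_that("species below the juvenile threshold are folded into adult-only", {
  sc <- sim_scenario()
  env <- simulate_environment(sc, 9)
  sim <- simulate_histories(sc, env, 9, emit_records = FALSE)
  ma <- sim$truth$marrays
  # artificially shrink one species' juvenile sample below the threshold
  keep <- ma$rayadito$juv$R
  ma$rayadito$juv$R[] <- 0L
  ma$rayadito$juv$R[1] <- 3L
  ma$rayadito$juv$m[] <- 0L
  ma$rayadito$juv$never[] <- 0L
  ma$rayadito$juv$never[1] <- 3L
  fit <- fit_cjs_community(ma, sim$truth$design, scenario_traits(sc),
                           config = list(chains = 2L, iters = 200L,
                                         burnin = 50L, thin = 1L), seed = 1)
  expect_false(fit$has_juv[["rayadito"]])
  expect_false("alpha_juv[rayadito]" %in% colnames(fit$draws))
})
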