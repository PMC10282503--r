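small_scenario <- function(...) {
  sim_scenario(T = 6, species = data.frame(
    name = c("resident", "migrant"),
    n_juv = c(120L, 0L), n_ad = c(150L, 90L),
    phi_juv = c(0.3, NA), phi_ad = c(0.45, 0.55), p = c(0.4, 0.3),
    MB = c(0L, 1L), BS = c(12, 20), stringsAsFactors = FALSE), ...)
}

test_that("a noiseless temperature trend aggregates to an exact linear slope", {
  sc <- sim_scenario(T = 10, env = list(tmin_noise_sd = 0, tmin_trend = 0.1))
  env <- simulate_environment(sc, seed = 2)
  w <- aggregate_weather(env$weather, sc$start_year:(sc$start_year + sc$T - 1))
  tt <- trend_test(w$temp)
  expect_equal(tt$slope, 0.1, tolerance = 1e-10)
})

test_that("environment simulation is deterministic given the seed", {
  sc <- small_scenario()
  e1 <- simulate_environment(sc, seed = 9)
  e2 <- simulate_environment(sc, seed = 9)
  expect_identical(e1, e2)
  e3 <- simulate_environment(sc, seed = 10)
  expect_false(identical(e1$weather$tmin_c, e3$weather$tmin_c))
})

test_that("winter precipitation matches the log-normal closed-form mean", {
  sc <- sim_scenario(T = 3)
  mu <- sc$env$precip_meanlog; sg <- sc$env$precip_sdlog
  daily_mean <- exp(mu + sg^2 / 2)
  daily_var <- (exp(sg^2) - 1) * exp(2 * mu + sg^2)
  reps <- 300
  sums <- vapply(seq_len(reps), function(r) {
    env <- simulate_environment(sc, seed = 5000 + r)
    aggregate_weather(env$weather, sc$start_year:(sc$start_year + 2))$precip[1]
  }, numeric(1))
  se <- sqrt(153 * daily_var / reps)
  expect_lt(abs(mean(sums) - 153 * daily_mean), 3 * se)
})

test_that("degenerate survival and detection produce the expected histories", {
  sc <- small_scenario(sigma_res = c(juv = 1e-8, ad = 1e-8, p = 1e-8))
  sc$species$phi_juv <- c(1 - 1e-12, NA)
  sc$species$phi_ad <- c(1 - 1e-12, 1 - 1e-12)
  sc$species$p <- c(1 - 1e-12, 1 - 1e-12)
  sc$beta$juv[] <- 0; sc$beta$ad[] <- 0; sc$beta$effort[] <- 0
  env <- simulate_environment(sc, 1)
  sim <- simulate_histories(sc, env, 1, emit_records = FALSE)
  H <- sim$truth$histories$H
  first <- sim$truth$histories$first
  for (i in seq_len(nrow(H)))
    expect_equal(unname(H[i, first[i]:sc$T]), rep(1L, sc$T - first[i] + 1))

  sc0 <- small_scenario(sigma_res = c(juv = 1e-8, ad = 1e-8, p = 1e-8))
  sc0$species$phi_juv <- c(1e-12, NA)
  sc0$species$phi_ad <- c(1e-12, 1e-12)
  sc0$beta$juv[] <- 0; sc0$beta$ad[] <- 0
  sim0 <- simulate_histories(sc0, env, 1, emit_records = FALSE)
  expect_true(all(rowSums(sim0$truth$histories$H) == 1))
})

test_that("one-interval recapture fraction obeys binomial moments", {
  sc <- sim_scenario(T = 3, species = data.frame(
    name = "only", n_juv = 10000L, n_ad = 0L, phi_juv = 0.3, phi_ad = 0.5,
    p = 0.4, MB = 0L, BS = 10, stringsAsFactors = FALSE),
    sigma_res = c(juv = 1e-9, ad = 1e-9, p = 1e-9))
  sc$beta$juv[] <- 0; sc$beta$ad[] <- 0; sc$beta$effort[] <- 0
  env <- simulate_environment(sc, 3)
  sim <- simulate_histories(sc, env, 3, emit_records = FALSE)
  ma <- sim$truth$marrays$only$juv
  # juveniles released at occasion 1 recaptured at occasion 2: phi_juv * p
  frac <- ma$m[1, 1] / ma$R[1]
  p_exp <- 0.3 * 0.4
  se <- sqrt(p_exp * (1 - p_exp) / ma$R[1])
  expect_lt(abs(frac - p_exp), 3 * se)
})

test_that("the default scenario matches the study design it emulates", {
  sc <- sim_scenario()
  expect_equal(sc$T, 20L)
  expect_equal(nrow(sc$species), 5L)
  expect_equal(sum(sc$species$MB), 1L)          # exactly one migrant
  # newly banded individuals per species equal the printed C columns
  expect_equal(sc$species$n_juv, c(323L, 375L, 0L, 0L, 772L))
  expect_equal(sc$species$n_ad, c(474L, 676L, 136L, 73L, 780L))
  # the migrant carries the planted precipitation and ENSO effects
  expect_equal(unname(sc$beta$juv["precip", sc$species$MB == 1]), 1.45)
  expect_equal(unname(sc$beta$juv["enso", sc$species$MB == 1]), -1.60)
  env <- simulate_environment(sc, 11)
  sim <- simulate_histories(sc, env, 11)
  cnt <- history_counts(sim$truth$histories)
  ord <- match(cnt$species, sc$species$name)
  # generated volumes equal the release schedules by construction
  expect_equal(cnt$C_juv + cnt$C_ad, sc$species$n_juv[ord] + sc$species$n_ad[ord])
  expect_equal(sort(filter_species(sim$truth$histories)), sort(sc$species$name))
})

test_that("ingesting emitted records reproduces the truth m-arrays exactly", {
  sc <- small_scenario()
  env <- simulate_environment(sc, 21)
  sim <- simulate_histories(sc, env, 21)
  f <- tempfile(fileext = ".csv")
  write.csv(sim$records, f, row.names = FALSE)
  rec <- read_captures(f)
  hist <- collapse_to_annual(rec, years = sc$start_year:(sc$start_year + sc$T - 1))
  ma <- build_marrays(hist)
  tm <- sim$truth$marrays
  for (s in names(ma)) for (age in c("juv", "ad")) {
    expect_equal(unname(ma[[s]][[age]]$m), unname(tm[[s]][[age]]$m))
    expect_equal(unname(ma[[s]][[age]]$never), unname(tm[[s]][[age]]$never))
    expect_equal(unname(ma[[s]][[age]]$R), unname(tm[[s]][[age]]$R))
  }
})

test_that("simulate_study writes every input table plus the truth sidecar", {
  sc <- small_scenario()
  dir <- tempfile()
  out <- simulate_study(sc, dir, seed = 4)
  for (f in c("banding.csv", "weather.csv", "mei.csv", "effort.csv",
              "traits.csv", "truth/true_rates.csv", "truth/true_params.json",
              "truth/marrays/manifest.json"))
    expect_true(file.exists(file.path(dir, f)))
  # same seed, fresh directory: byte-identical banding file
  dir2 <- tempfile()
  simulate_study(sc, dir2, seed = 4)
  expect_identical(readLines(file.path(dir, "banding.csv")),
                   readLines(file.path(dir2, "banding.csv")))
  unlink(c(dir, dir2), recursive = TRUE)
})
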