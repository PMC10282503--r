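test_that("linear predictors reduce to inverse-logit of the intercepts", {
  des <- make_design(6)
  p <- cjs_params("sp", TRUE, 6)
  rates <- linear_predictors(p, des)
  expect_equal(unname(rates$phi_juv[, 1]), rep(0.5, 5))
  expect_equal(unname(rates$phi_ad[, 1]), rep(0.5, 5))
  expect_equal(unname(rates$p[, 1]), rep(0.5, 5))
})

test_that("a precipitation slope of 1.45 at precip_z = 1 gives phi near 0.81", {
  des <- make_design(6, precip_z = rep(1, 5))
  p <- cjs_params("sp", TRUE, 6)
  p$beta$juv["precip", 1] <- 1.45
  rates <- linear_predictors(p, des)
  expect_equal(unname(rates$phi_juv[, 1]), rep(1 / (1 + exp(-1.45)), 5))
  expect_equal(unname(rates$phi_juv[1, 1]), 0.8100, tolerance = 1e-4)
})

test_that("rates stay strictly inside (0,1) for wild parameter values", {
  des <- make_design(8, seed = 3)
  set.seed(9)
  for (r in 1:20) {
    p <- cjs_params(c("a", "b"), c(TRUE, FALSE), 8)
    p$alpha$ad[] <- rnorm(2, 0, 5)
    p$alpha$juv[1] <- rnorm(1, 0, 5)
    p$alpha$p[] <- rnorm(2, 0, 5)
    p$beta$ad[] <- rnorm(8, 0, 3)
    p$eps$ad[] <- rnorm(14, 0, 2)
    rates <- linear_predictors(p, des)
    expect_true(all(rates$phi_ad > 0 & rates$phi_ad < 1))
    expect_true(all(rates$p > 0 & rates$p < 1))
  }
})

test_that("the hierarchical prior respects its support and slope density", {
  tr <- data.frame(species = "sp", MB = 0, BS_z = 0)
  p <- cjs_params("sp", TRUE, 5)
  base <- hierarchical_logprior(p, tr)
  expect_true(is.finite(base))
  p_bad <- p; p_bad$sigma$ad[1] <- 10.5
  expect_identical(hierarchical_logprior(p_bad, tr), -Inf)
  p_bad2 <- p; p_bad2$sigma_mu[1] <- -0.1
  expect_identical(hierarchical_logprior(p_bad2, tr), -Inf)
  # moving one slope from 0 to b changes the prior by the normal log-ratio
  p2 <- p; p2$beta$ad["temp", 1] <- 1.7
  expect_equal(hierarchical_logprior(p2, tr) - base,
               dnorm(1.7, 0, sqrt(10), log = TRUE) - dnorm(0, 0, sqrt(10), log = TRUE),
               tolerance = 1e-12)
  # symmetric in the hyper-mean when traits are centered
  pm <- p; pm$mu[["phi_ad"]] <- 0.8; pm$alpha$ad[1] <- 0.8
  pn <- p; pn$mu[["phi_ad"]] <- -0.8; pn$alpha$ad[1] <- -0.8
  expect_equal(hierarchical_logprior(pm, tr), hierarchical_logprior(pn, tr),
               tolerance = 1e-12)
})

test_that("m-array cell probabilities match the worked single-cohort example", {
  pr <- marray_cell_probs(rep(0.6, 2), rep(0.6, 2), rep(0.5, 2))
  expect_equal(unname(pr[1, ]), c(0.3, 0.09, 0.61), tolerance = 1e-12)
  # rows always sum to one
  set.seed(14)
  for (r in 1:20) {
    pr <- marray_cell_probs(runif(9), runif(9), runif(9))
    expect_equal(unname(rowSums(pr)), rep(1, 9), tolerance = 1e-12)
  }
})

test_that("marray_loglik reproduces the hand-computed example with constants", {
  # two releases at occasion 1 only: one first re-encountered at occasion 2,
  # one never re-encountered; cell probabilities (0.3, 0.09, 0.61)
  ma <- structure(list(sp = list(
    juv = list(m = matrix(0L, 2, 2), never = c(0L, 0L), R = c(0L, 0L)),
    ad = list(m = matrix(c(1L, 0L, 0L, 0L), 2, 2), never = c(1L, 0L),
              R = c(2L, 0L)),
    has_juv = FALSE)), years = 2001:2003, class = "marray_set")
  rates <- list(phi_juv = matrix(0.6, 2, 1), phi_ad = matrix(0.6, 2, 1),
                p = matrix(0.5, 2, 1))
  ll <- marray_loglik(ma, rates)
  expect_equal(as.numeric(ll), log(2) + log(0.3) + log(0.61), tolerance = 1e-12)
  expect_equal(as.numeric(marray_loglik(ma, rates, include_const = FALSE)),
               log(0.3) + log(0.61), tolerance = 1e-12)
})

test_that("zero survival makes never-re-encountered data certain", {
  hist <- rand_histories(30, 5, p_det = 0, seed = 6)   # no recaptures
  ma <- build_marrays(hist)
  eps_rate <- 1e-12
  rates <- list(phi_juv = matrix(eps_rate, 4, 1), phi_ad = matrix(eps_rate, 4, 1),
                p = matrix(0.5, 4, 1))
  ll <- marray_loglik(ma, rates, include_const = FALSE)
  expect_equal(as.numeric(ll), 0, tolerance = 1e-9)
})

test_that("the likelihood only depends on counts, not individual order", {
  hist <- rand_histories(200, 6, seed = 44)
  set.seed(1); perm <- sample(nrow(hist$H))
  hist2 <- structure(list(H = hist$H[perm, ], species = hist$species[perm],
                          age_at_first = hist$age_at_first[perm],
                          first = hist$first[perm], years = hist$years),
                     class = "annual_histories")
  rates <- list(phi_juv = matrix(runif(5), 5, 1), phi_ad = matrix(runif(5), 5, 1),
                p = matrix(runif(5), 5, 1))
  expect_equal(as.numeric(marray_loglik(build_marrays(hist), rates)),
               as.numeric(marray_loglik(build_marrays(hist2), rates)),
               tolerance = 1e-10)
})

test_that("m-array likelihood equals per-individual enumeration", {
  set.seed(77)
  for (r in 1:10) {
    T <- sample(3:4, 1)
    hist <- rand_histories(sample(2:5, 1), T)
    phi_j <- runif(T - 1, 0.05, 0.95)
    phi_a <- runif(T - 1, 0.05, 0.95)
    p <- runif(T - 1, 0.05, 0.95)
    rates <- list(phi_juv = matrix(phi_j, ncol = 1),
                  phi_ad = matrix(phi_a, ncol = 1), p = matrix(p, ncol = 1))
    ll <- marray_loglik(build_marrays(hist), rates, include_const = FALSE)
    expect_equal(as.numeric(ll), enum_loglik(hist, phi_j, phi_a, p),
                 tolerance = 1e-10)
  }
})

test_that("the joint log-posterior is finite on prior-plausible draws", {
  set.seed(123)
  sc <- sim_scenario()
  env <- simulate_environment(sc, 3)
  sim <- simulate_histories(sc, env, 3, emit_records = FALSE)
  ma <- sim$truth$marrays; des <- sim$truth$design
  tr <- scenario_traits(sc)
  species <- names(ma)
  has_juv <- vapply(ma, function(a) sum(a$juv$R) > 0, logical(1))
  map <- cjs_param_map(species, has_juv, sc$T)
  for (r in 1:5) {
    th <- rnorm(nrow(map), 0, 0.5)
    th[map$kind %in% c(2L, 6L)] <- runif(sum(map$kind %in% c(2L, 6L)), 0.05, 3)
    p <- vector_to_params(th, map, species, has_juv, sc$T)
    expect_true(is.finite(cjs_logpost(p, ma, des, tr)))
  }
})
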