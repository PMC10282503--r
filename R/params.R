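## Flat parameter layout shared by the R reference path and the compiled
## sampler. Kinds: 1 hyper-mean, 2 hyper-SD, 3 community trait slope,
## 4 species intercept, 5 species slope, 6 residual SD, 7 temporal
## residual. Ages: 1 juvenile survival, 2 adult survival, 3 recapture.

#' Flat parameter map of the hierarchical CJS model
#'
#' Enumerates every scalar parameter of the model for a given problem
#' size, in the fixed order used by the sampler and the posterior draw
#' matrices.
#'
#' @param species character vector of species codes.
#' @param has_juv logical per species.
#' @param T number of occasions.
#' @param literal_intercepts if `TRUE`, hyper-SDs, trait slopes and
#'   species intercepts are dropped (the literal regression form).
#' @return data frame with columns `name`, `kind`, `sp` (0 = community),
#'   `t` (slope index / residual interval, 0 = none), `age`.
#' @export
cjs_param_map <- function(species, has_juv, T, literal_intercepts = FALSE) {
  S <- length(species)
  rows <- list()
  add <- function(name, kind, sp, t, age)
    rows[[length(rows) + 1L]] <<- data.frame(name = name, kind = kind,
                                             sp = sp, t = t, age = age)
  ages3 <- c("phi_juv", "phi_ad", "p")
  for (a in 1:3) add(paste0("mu_", ages3[a]), 1L, 0L, 0L, a)
  if (!literal_intercepts) {
    for (a in 1:3) add(paste0("sigma_mu_", ages3[a]), 2L, 0L, 0L, a)
    for (a in 1:2) for (tr in 1:2)
      add(paste0("b", c("MB", "BS")[tr], "_", c("juv", "ad")[a]), 3L, 0L, tr, a)
  }
  slope_names <- c("year", "temp", "precip", "enso")
  for (s in seq_len(S)) {
    ages <- if (has_juv[s]) 1:3 else 2:3
    if (!literal_intercepts)
      for (a in ages) add(sprintf("alpha_%s[%s]", c("juv", "ad", "p")[a], species[s]),
                          4L, s, 0L, a)
    for (a in intersect(ages, 1:2)) for (k in 1:4)
      add(sprintf("b_%s_%s[%s]", slope_names[k], c("juv", "ad")[a], species[s]),
          5L, s, k, a)
    add(sprintf("b_effort[%s]", species[s]), 5L, s, 1L, 3L)
    for (a in ages) add(sprintf("sigma_%s[%s]", c("juv", "ad", "p")[a], species[s]),
                        6L, s, 0L, a)
    for (a in ages) for (t in seq_len(T - 1L))
      add(sprintf("eps_%s[%d,%s]", c("juv", "ad", "p")[a], t, species[s]),
          7L, s, t, a)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert between flat vectors and structured parameters
#'
#' @param params a `cjs_params` structure.
#' @param map a parameter map from [cjs_param_map()].
#' @return `params_to_vector()`: a named numeric vector in map order.
#' @export
params_to_vector <- function(params, map) {
  ages3 <- c("juv", "ad", "p")
  v <- numeric(nrow(map))
  for (i in seq_len(nrow(map))) {
    k <- map$kind[i]; s <- map$sp[i]; t <- map$t[i]; a <- map$age[i]
    v[i] <- switch(k,
      params$mu[[a]],
      params$sigma_mu[[a]],
      params$beta_trait[[ages3[a]]][[t]],
      params$alpha[[ages3[a]]][[s]],
      if (a == 3L) params$beta$effort[[s]] else params$beta[[ages3[a]]][t, s],
      params$sigma[[ages3[a]]][[s]],
      params$eps[[ages3[a]]][t, s])
  }
  setNames(v, map$name)
}

#' @rdname params_to_vector
#' @param theta named numeric vector in map order.
#' @param species,has_juv,T problem dimensions (see [cjs_params()]).
#' @return `vector_to_params()`: a `cjs_params` structure.
#' @export
vector_to_params <- function(theta, map, species, has_juv, T) {
  p <- cjs_params(species, has_juv, T)
  ages3 <- c("juv", "ad", "p")
  for (i in seq_len(nrow(map))) {
    k <- map$kind[i]; s <- map$sp[i]; t <- map$t[i]; a <- map$age[i]
    val <- theta[[i]]
    if (k == 1L) p$mu[[a]] <- val
    else if (k == 2L) p$sigma_mu[[a]] <- val
    else if (k == 3L) p$beta_trait[[ages3[a]]][[t]] <- val
    else if (k == 4L) p$alpha[[ages3[a]]][[s]] <- val
    else if (k == 5L) {
      if (a == 3L) p$beta$effort[[s]] <- val else p$beta[[ages3[a]]][t, s] <- val
    } else if (k == 6L) p$sigma[[ages3[a]]][[s]] <- val
    else p$eps[[ages3[a]]][t, s] <- val
  }
  p
}
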