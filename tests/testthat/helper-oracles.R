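# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (per-individual scans, recursions,
# brute-force window searches) and independent of the package's
# implementation paths.

# log-probability of one capture history by direct per-individual
# recursion (chi = probability of never being seen after an occasion)
enum_history_logprob <- function(h, age_first, phi_j, phi_a, p) {
  T <- length(h)
  det <- which(h == 1)
  f <- det[1]
  L <- max(det)
  lp <- 0
  if (L > f) for (t in f:(L - 1)) {
    phi <- if (age_first == "juvenile" && t == f) phi_j[t] else phi_a[t]
    lp <- lp + log(phi) + log(if (h[t + 1] == 1) p[t] else 1 - p[t])
  }
  chi <- function(t, isjuv) {
    if (t == T) return(1)
    phi <- if (isjuv) phi_j[t] else phi_a[t]
    (1 - phi) + phi * (1 - p[t]) * chi(t + 1, FALSE)
  }
  lp + log(chi(L, age_first == "juvenile" && L == f))
}

# total log-likelihood of a set of histories by enumeration
enum_loglik <- function(hist, phi_j, phi_a, p) {
  sum(vapply(seq_len(nrow(hist$H)), function(i)
    enum_history_logprob(hist$H[i, ], hist$age_at_first[i], phi_j, phi_a, p),
    numeric(1)))
}

# log multinomial coefficients by an independent per-individual release
# scan (no use of build_marrays)
enum_logconst <- function(hist) {
  T <- ncol(hist$H)
  keys <- character(0)
  for (i in seq_len(nrow(hist$H))) {
    det <- which(hist$H[i, ] == 1)
    for (k in seq_along(det)) {
      rel <- det[k]
      if (rel >= T) next
      age <- if (k == 1 && hist$age_at_first[i] == "juvenile") "j" else "a"
      outcome <- if (k < length(det)) as.character(det[k + 1]) else "never"
      keys <- c(keys, paste(age, rel, outcome))
    }
  }
  tab <- table(keys)
  rel_tab <- table(sub(" [^ ]+$", "", keys))
  sum(lgamma(rel_tab + 1)) - sum(lgamma(tab + 1))
}

# random single-species histories with guaranteed first detections
rand_histories <- function(n, T, p_det = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  first <- sample(seq_len(T), n, replace = TRUE)
  H <- matrix(0L, n, T)
  H[cbind(seq_len(n), first)] <- 1L
  for (i in seq_len(n)) {
    if (first[i] < T)
      H[i, (first[i] + 1):T] <- stats::rbinom(T - first[i], 1L, p_det)
  }
  structure(list(H = H, species = rep("sp", n),
                 age_at_first = sample(c("juvenile", "adult"), n, replace = TRUE),
                 first = first, years = seq(2001, length.out = T)),
            class = "annual_histories")
}

# naive per-individual m-array recount, independent of build_marrays
recount_marrays <- function(hist) {
  T <- ncol(hist$H)
  mk <- function() list(m = matrix(0L, T - 1, T - 1), never = integer(T - 1),
                        R = integer(T - 1))
  out <- list(juv = mk(), ad = mk())
  for (i in seq_len(nrow(hist$H))) {
    det <- which(hist$H[i, ] == 1)
    for (k in seq_along(det)) {
      rel <- det[k]
      if (rel >= T) next
      a <- if (k == 1 && hist$age_at_first[i] == "juvenile") "juv" else "ad"
      out[[a]]$R[rel] <- out[[a]]$R[rel] + 1L
      if (k < length(det)) {
        j <- det[k + 1]
        out[[a]]$m[rel, j - 1] <- out[[a]]$m[rel, j - 1] + 1L
      } else out[[a]]$never[rel] <- out[[a]]$never[rel] + 1L
    }
  }
  out
}

# brute-force shortest window containing ceiling(prob * n) sorted draws
brute_hdi <- function(draws, prob = 0.89) {
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(prob * n)
  best <- c(x[1], x[k]); bw <- x[k] - x[1]
  for (i in seq_len(n - k + 1)) {
    w <- x[i + k - 1] - x[i]
    if (w < bw) { bw <- w; best <- c(x[i], x[i + k - 1]) }
  }
  best
}

# 2x2 chi-squared by the closed formula n(ad - bc)^2 / (r1 r2 c1 c2)
hand_chisq_2x2 <- function(tab) {
  n <- sum(tab)
  n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
}

# hand-built standardized covariate design for model-level tests
make_design <- function(T, seed = 1, precip_z = NULL) {
  set.seed(seed)
  zs <- function(x) (x - mean(x)) / sd(x)
  iv <- data.frame(interval = seq_len(T - 1),
                   year = as.numeric(seq_len(T - 1)),
                   temp = rnorm(T - 1, 2, 1), precip = rlnorm(T - 1, 5, 0.3),
                   enso = rnorm(T - 1))
  for (v in c("year", "temp", "precip", "enso")) iv[[paste0(v, "_z")]] <- zs(iv[[v]])
  if (!is.null(precip_z)) iv$precip_z <- precip_z
  eff <- rlnorm(T, 7, 0.2)
  structure(list(years = seq(2001, length.out = T), intervals = iv,
                 effort = eff, effort_z = zs(eff),
                 cor_climate = diag(3)),
            class = "cjs_design")
}

# constant-rate null CJS simulator (new cohort released at each occasion)
sim_null_cjs <- function(n_new, T, phi, p) {
  n <- n_new * T
  first <- rep(seq_len(T), each = n_new)
  H <- matrix(0L, n, T)
  H[cbind(seq_len(n), first)] <- 1L
  for (i in seq_len(n)) if (first[i] < T) for (t in first[i]:(T - 1)) {
    if (stats::runif(1) > phi) break
    if (stats::runif(1) < p) H[i, t + 1] <- 1L
  }
  H
}

# alphabetically ordered trait table for the default scenario
scenario_traits <- function(sc) {
  tr <- data.frame(species = sc$species$name, MB = sc$species$MB,
                   BS = sc$species$BS)
  tr <- tr[order(tr$species), ]
  tr$BS_z <- (tr$BS - mean(tr$BS)) / sd(tr$BS)
  tr
}
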