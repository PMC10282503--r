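## U-CARE-style goodness-of-fit tests for single-state CJS capture
## histories: transience (3.SR), first-re-encounter timing (3.Sm, the
## component sometimes labeled 2.Sm), immediate trap-dependence (2.CT) and
## re-encounter-timing dependence (2.CL), plus the overall test.
##
## Each component follows the classical sequential factorization of the
## capture-history multinomial, so per-occasion tables are
## quasi-independent under the null CJS model (odds ratios of 1;
## conditioning factors cancel) and the summed chi-squared statistics are
## asymptotically chi-squared on the summed degrees of freedom. Tables
## are pooled until all expected counts reach 2 and skipped when they
## cannot; degrees of freedom are reduced accordingly.

# chi-squared statistic with column pooling (merge the offending column
# into its left neighbor until all expected counts >= min_exp); returns
# NULL when the table cannot support a test
pooled_chisq <- function(tab, min_exp = 2) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NULL)
  expected <- function(t) outer(rowSums(t), colSums(t)) / sum(t)
  while (ncol(tab) > 2L && any(expected(tab) < min_exp)) {
    ex <- expected(tab)
    j <- max(which(apply(ex < min_exp, 2L, any)))   # rightmost offender
    tgt <- if (j == 1L) 2L else j - 1L
    tab[, tgt] <- tab[, tgt] + tab[, j]
    tab <- tab[, -j, drop = FALSE]
  }
  ex <- expected(tab)
  if (any(ex < min_exp)) return(NULL)
  stat <- sum((tab - ex)^2 / ex)
  list(statistic = stat, df = (nrow(tab) - 1L) * (ncol(tab) - 1L), table = tab)
}

# normalize input to a binary detection matrix
gof_matrix <- function(histories) {
  if (inherits(histories, "annual_histories")) histories$H else as.matrix(histories)
}

gof_component <- function(per_occ) {
  keep <- !vapply(per_occ, is.null, logical(1))
  stat <- sum(vapply(per_occ[keep], `[[`, numeric(1), "statistic"))
  df <- sum(vapply(per_occ[keep], `[[`, numeric(1), "df"))
  list(statistic = stat, df = df,
       p_value = if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_,
       tables = per_occ[keep])
}

empty_component <- function()
  list(statistic = 0, df = 0L, p_value = NA_real_, tables = list())

#' Transience test (3.SR)
#'
#' For each occasion, compares animals encountered there for the first
#' time with previously marked animals on whether they are ever
#' re-encountered afterwards. An excess of never-again-seen newcomers
#' indicates transient individuals.
#'
#' @param histories an `annual_histories` object (one species) or a binary
#'   detection matrix (individuals x occasions).
#' @return list with `statistic` (summed chi-squared), `df`, `p_value` and
#'   the per-occasion `tables` that entered the sum.
#' @export
test_3sr <- function(histories) {
  H <- gof_matrix(histories)
  T <- ncol(H)
  if (T < 3L || nrow(H) == 0L) return(empty_component())
  first <- apply(H, 1L, function(h) which(h == 1L)[1L])
  per_occ <- lapply(2:(T - 1L), function(i) {
    at_i <- H[, i] == 1L
    if (!any(at_i)) return(NULL)
    new <- first[at_i] == i
    reseen <- rowSums(H[at_i, (i + 1L):T, drop = FALSE]) > 0L
    pooled_chisq(table(factor(new, c(TRUE, FALSE)), factor(reseen, c(TRUE, FALSE))))
  })
  gof_component(per_occ)
}

#' First re-encounter timing test (3.Sm)
#'
#' Among animals encountered at an occasion and re-encountered later,
#' compares the occasion of next encounter between newly and previously
#' marked animals. (The component sometimes labeled 2.Sm.)
#'
#' @inheritParams test_3sr
#' @return as [test_3sr()].
#' @export
test_3sm <- function(histories) {
  H <- gof_matrix(histories)
  T <- ncol(H)
  if (T < 4L || nrow(H) == 0L) return(empty_component())
  first <- apply(H, 1L, function(h) which(h == 1L)[1L])
  per_occ <- lapply(2:(T - 2L), function(i) {
    at_i <- which(H[, i] == 1L)
    if (length(at_i) == 0L) return(NULL)
    nxt <- apply(H[at_i, (i + 1L):T, drop = FALSE], 1L, function(h) {
      w <- which(h == 1L)
      if (length(w)) w[1L] else NA_integer_
    })
    keep <- !is.na(nxt)
    if (!any(keep)) return(NULL)
    pooled_chisq(table(factor(first[at_i][keep] == i, c(TRUE, FALSE)),
                       factor(nxt[keep], seq_len(T - i))))
  })
  gof_component(per_occ)
}

#' Immediate trap-dependence test (2.CT)
#'
#' For each pair of consecutive occasions `(i, i+1)`, cross-tabulates
#' detection at `i` with detection at `i+1` among animals known alive
#' across the pair (seen at or before `i` and seen at or after `i+1`).
#' Under the null the table's odds ratio is 1 (the conditioning factors
#' cancel). A positive association indicates trap-happiness, a negative
#' one trap-shyness.
#'
#' @inheritParams test_3sr
#' @return as [test_3sr()], plus `z` (signed per-occasion z-statistics,
#'   positive for trap-happiness).
#' @export
test_2ct <- function(histories) {
  H <- gof_matrix(histories)
  T <- ncol(H)
  if (T < 3L || nrow(H) == 0L) return(c(empty_component(), list(z = numeric(0))))
  zs <- numeric(0)
  per_occ <- lapply(2:(T - 1L), function(i) {
    before <- rowSums(H[, 1:i, drop = FALSE]) > 0L
    after <- rowSums(H[, (i + 1L):T, drop = FALSE]) > 0L
    k <- before & after
    if (!any(k)) return(NULL)
    res <- pooled_chisq(table(factor(H[k, i] == 1L, c(TRUE, FALSE)),
                              factor(H[k, i + 1L] == 1L, c(TRUE, FALSE))))
    if (!is.null(res)) {
      tb <- res$table
      if (all(dim(tb) == c(2L, 2L))) {
        sgn <- sign(tb[1L, 1L] * tb[2L, 2L] - tb[1L, 2L] * tb[2L, 1L])
        zs <<- c(zs, sgn * sqrt(res$statistic))
      }
    }
    res
  })
  c(gof_component(per_occ), list(z = zs))
}

#' Re-encounter timing dependence test (2.CL)
#'
#' Among animals seen at or before an occasion `i`, not seen at `i+1`,
#' and re-encountered at `i+2` or later, tests whether the timing of that
#' next encounter depends on detection at `i` itself.
#'
#' @inheritParams test_3sr
#' @return as [test_3sr()].
#' @export
test_2cl <- function(histories) {
  H <- gof_matrix(histories)
  T <- ncol(H)
  if (T < 5L || nrow(H) == 0L) return(empty_component())
  per_occ <- lapply(2:(T - 3L), function(i) {
    before <- rowSums(H[, 1:i, drop = FALSE]) > 0L
    after <- rowSums(H[, (i + 2L):T, drop = FALSE]) > 0L
    k <- which(before & after & H[, i + 1L] == 0L)
    if (length(k) == 0L) return(NULL)
    nxt <- apply(H[k, (i + 2L):T, drop = FALSE], 1L, function(h) which(h == 1L)[1L])
    pooled_chisq(table(factor(H[k, i] == 1L, c(TRUE, FALSE)),
                       factor(nxt, seq_len(T - i - 1L))))
  })
  gof_component(per_occ)
}

#' Overall goodness-of-fit test for one species
#'
#' Sums the four component statistics (3.SR, 3.Sm, 2.CT, 2.CL) and their
#' degrees of freedom; the overall p-value is the chi-squared upper tail.
#'
#' @inheritParams test_3sr
#' @return list of class `gof_result` with the four components and
#'   `overall` (`statistic`, `df`, `p_value`).
#' @export
overall_gof <- function(histories) {
  comps <- list(`3.SR` = test_3sr(histories), `3.Sm` = test_3sm(histories),
                `2.CT` = test_2ct(histories), `2.CL` = test_2cl(histories))
  stat <- sum(vapply(comps, `[[`, numeric(1), "statistic"))
  df <- sum(vapply(comps, `[[`, numeric(1), "df"))
  structure(c(comps, list(overall = list(
    statistic = stat, df = df,
    p_value = if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_))),
    class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("CJS goodness-of-fit components:\n")
  for (nm in c("3.SR", "3.Sm", "2.CT", "2.CL", "overall")) {
    cm <- x[[nm]]
    cat(sprintf("  %-8s chi2 = %7.3f  df = %3d  p = %s\n", nm,
                cm$statistic, cm$df,
                if (is.na(cm$p_value)) "NA" else sprintf("%.4f", cm$p_value)))
  }
  invisible(x)
}

#' Goodness-of-fit suite per species
#'
#' Runs the overall test on each species' pooled-age capture histories.
#'
#' @param histories an `annual_histories` object (any mix of species).
#' @return data frame with one row per species x component (including
#'   `overall`): `statistic`, `df`, `p_value`; the full `gof_result`
#'   objects are attached as attribute `results`.
#' @export
cjs_gof <- function(histories) {
  sp <- sort(unique(histories$species))
  results <- lapply(sp, function(s) overall_gof(subset_species(histories, s)))
  names(results) <- sp
  rows <- do.call(rbind, lapply(sp, function(s) {
    r <- results[[s]]
    do.call(rbind, lapply(c("3.SR", "3.Sm", "2.CT", "2.CL", "overall"), function(nm)
      data.frame(species = s, component = nm, statistic = r[[nm]]$statistic,
                 df = r[[nm]]$df, p_value = r[[nm]]$p_value)))
  }))
  rownames(rows) <- NULL
  attr(rows, "results") <- results
  rows
}
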