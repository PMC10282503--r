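## Banding-record ingestion and capture-history construction.
##
## Raw mist-netting records (one row per handling event) are collapsed to
## annual breeding-season capture histories, filtered to species with
## adequate samples, and summarized as age-structured m-arrays, the
## sufficient statistic of the Cormack-Jolly-Seber likelihood.

#' Read banding records from CSV
#'
#' Reads a banding file with one row per capture/recapture event. Rows with
#' unparseable dates or missing band/species fields are dropped and counted;
#' the drop count is attached as an attribute and logged when
#' `options(cjscommunity.verbose = TRUE)`.
#'
#' @param path path to a CSV file with a header row.
#' @param schema named list mapping the internal column names `band_id`,
#'   `species`, `date`, `age_code`, `body_mass` to the file's column names.
#'   Defaults to identical names. A `site` column, if present, is ignored:
#'   netting sites are treated as a single site.
#' @return a `data.frame` of class `capture_records` with columns
#'   `band_id`, `species`, `date` (`Date`), `age_code` (one of `"juvenile"`,
#'   `"adult"`, `"unknown"`) and `body_mass` (grams, `NA` allowed), with
#'   attribute `n_dropped`.
#' @export
read_captures <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("banding file not found: ", path, call. = FALSE)
  schema <- utils::modifyList(
    list(band_id = "band_id", species = "species", date = "date",
         age_code = "age_code", body_mass = "body_mass"),
    schema %||% list())
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty banding file: ", path, call. = FALSE)
  required <- c("band_id", "species", "date", "age_code")
  missing_cols <- setdiff(unlist(schema[required]), names(raw))
  if (length(missing_cols))
    stop("missing required column(s) in banding file: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  rec <- data.frame(
    band_id  = as.character(raw[[schema$band_id]]),
    species  = as.character(raw[[schema$species]]),
    date     = as.Date(as.character(raw[[schema$date]]), format = "%Y-%m-%d"),
    age_code = tolower(as.character(raw[[schema$age_code]])),
    body_mass = if (schema$body_mass %in% names(raw))
      suppressWarnings(as.numeric(raw[[schema$body_mass]])) else NA_real_,
    stringsAsFactors = FALSE)
  bad_date <- is.na(rec$date)
  bad_id   <- is.na(rec$band_id) | rec$band_id == ""
  bad_sp   <- is.na(rec$species) | rec$species == ""
  bad_age  <- !rec$age_code %in% c("juvenile", "adult", "unknown")
  drop <- bad_date | bad_id | bad_sp | bad_age
  if (any(drop))
    cjs_log("read_captures: dropped %d of %d rows (%d bad date, %d bad id, %d bad species, %d bad age code)",
            sum(drop), nrow(rec), sum(bad_date), sum(bad_id), sum(bad_sp), sum(bad_age))
  rec <- rec[!drop, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "n_dropped") <- sum(drop)
  class(rec) <- c("capture_records", "data.frame")
  rec
}

# Season year label: a breeding season spanning Sept(Y)-Mar(Y+1) is labeled Y.
# Months at or after the season's first month belong to that calendar year's
# season; earlier months belong to the previous year's season.
season_year <- function(date, season_months = c(9:12, 1:3)) {
  start_month <- season_months[1L]
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  ifelse(m >= start_month, y, y - 1L)
}

#' Collapse banding records to annual capture histories
#'
#' Keeps only records whose month lies in the breeding-season window,
#' labels each record with its season year (a season spanning the calendar
#' year boundary is labeled by its starting year), and collapses multiple
#' handlings of one bird within one season to a single detection. A bird is
#' a juvenile release if any record within its first season carries age code
#' `"juvenile"`; unknown-age birds are treated as adults.
#'
#' @param records a `capture_records` data frame (see [read_captures()]),
#'   or any data frame with the same columns.
#' @param season integer months of the breeding season, beginning with the
#'   starting month (default September through March).
#' @param years integer vector of season-year labels defining the study
#'   occasions (default: full observed range).
#' @return an object of class `annual_histories`: a list with the n-by-T
#'   binary detection matrix `H`, per-individual `species`, `age_at_first`,
#'   `first` (first-detection occasion index) and the occasion labels
#'   `years`.
#' @export
collapse_to_annual <- function(records, season = c(9:12, 1:3), years = NULL) {
  if (length(season) == 0L) stop("empty season month set", call. = FALSE)
  if (!all(season %in% 1:12)) stop("season months must be in 1..12", call. = FALSE)
  m <- as.integer(format(records$date, "%m"))
  keep <- m %in% season
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) {
    years <- years %||% integer(0)
    return(structure(list(H = matrix(0L, 0L, length(years)),
                          species = character(0), age_at_first = character(0),
                          first = integer(0), years = as.integer(years)),
                     class = "annual_histories"))
  }
  rec$occ_year <- season_year(rec$date, season)
  years <- as.integer(years %||% seq(min(rec$occ_year), max(rec$occ_year)))
  rec <- rec[rec$occ_year %in% years, , drop = FALSE]
  T <- length(years)
  ids <- unique(rec$band_id)
  H <- matrix(0L, length(ids), T, dimnames = list(ids, years))
  occ <- match(rec$occ_year, years)
  H[cbind(match(rec$band_id, ids), occ)] <- 1L
  first <- apply(H, 1L, function(h) which(h == 1L)[1L])
  species <- rec$species[match(ids, rec$band_id)]
  # age at first capture: juvenile iff any record within the first season
  # says juvenile; unknown-age birds are adults
  age_at_first <- vapply(seq_along(ids), function(i) {
    ri <- rec[rec$band_id == ids[i] & occ == first[i], , drop = FALSE]
    codes <- unique(ri$age_code)
    if ("juvenile" %in% codes) {
      if (any(codes != "juvenile"))
        cjs_log("conflicting age codes for %s in first season: resolved to juvenile", ids[i])
      "juvenile"
    } else "adult"
  }, character(1))
  structure(list(H = H, species = species, age_at_first = age_at_first,
                 first = as.integer(first), years = years),
            class = "annual_histories")
}

#' @export
print.annual_histories <- function(x, ...) {
  cat("Annual capture histories:", nrow(x$H), "individuals,",
      length(x$years), "occasions (",
      if (length(x$years)) paste0(min(x$years), "-", max(x$years)) else "",
      ")\n", sep = " ")
  tab <- table(x$species)
  for (s in names(tab)) cat("  ", s, ": ", tab[[s]], " individuals\n", sep = "")
  invisible(x)
}

#' Filter species by sample-size thresholds
#'
#' A species is retained iff at least `min_captures` unique individuals were
#' captured and at least `min_recaptures` individuals were recaptured at a
#' later occasion. Counts are individual-level, not event-level.
#'
#' @param histories an `annual_histories` object.
#' @param min_captures minimum number of captured individuals (default 50).
#' @param min_recaptures minimum number of recaptured individuals (default 4).
#' @return character vector of retained species codes, alphabetical.
#' @export
filter_species <- function(histories, min_captures = 50, min_recaptures = 4) {
  stopifnot(min_captures >= 0, min_recaptures >= 0)
  n_det <- rowSums(histories$H)
  sp <- sort(unique(histories$species))
  keep <- vapply(sp, function(s) {
    i <- histories$species == s
    sum(i) >= min_captures && sum(n_det[i] > 1L) >= min_recaptures
  }, logical(1))
  sp[keep]
}

#' Subset annual histories to a set of species
#'
#' @param histories an `annual_histories` object.
#' @param species character vector of species codes to keep.
#' @return an `annual_histories` object restricted to those species.
#' @export
subset_species <- function(histories, species) {
  i <- histories$species %in% species
  structure(list(H = histories$H[i, , drop = FALSE],
                 species = histories$species[i],
                 age_at_first = histories$age_at_first[i],
                 first = histories$first[i], years = histories$years),
            class = "annual_histories")
}

#' Build age-structured m-arrays from annual histories
#'
#' Summarizes capture histories as release/first-recapture count matrices,
#' the sufficient statistic of the CJS likelihood. A bird first released as
#' a juvenile enters the juvenile m-array for its first release only; every
#' re-release, and every first release of an adult (or unknown-age) bird,
#' enters the adult m-array. `m[i, j]` counts birds released at occasion
#' `i` first re-encountered at occasion `j > i`; `never[i]` counts those
#' never re-encountered; releases at the final occasion are not releases
#' (no later occasion exists).
#'
#' @param histories an `annual_histories` object (any mix of species).
#' @return an object of class `marray_set`: a named list (one element per
#'   species, alphabetical) of lists with components `juv` and `ad`, each a
#'   list `m` ((T-1)-by-(T-1) matrix, columns = recapture occasions 2..T),
#'   `never`, `R` (length T-1), plus `has_juv`; attribute `years`.
#' @export
build_marrays <- function(histories) {
  T <- length(histories$years)
  if (T < 2L) stop("need at least 2 occasions to build m-arrays", call. = FALSE)
  sp <- sort(unique(histories$species))
  empty <- function() list(
    m = matrix(0L, T - 1L, T - 1L,
               dimnames = list(histories$years[-T], histories$years[-1L])),
    never = setNames(integer(T - 1L), histories$years[-T]),
    R = setNames(integer(T - 1L), histories$years[-T]))
  out <- lapply(sp, function(s) list(juv = empty(), ad = empty(), has_juv = FALSE))
  names(out) <- sp
  for (i in seq_len(nrow(histories$H))) {
    h <- histories$H[i, ]
    det <- which(h == 1L)
    if (length(det) == 0L) stop("history with no detections", call. = FALSE)
    if (det[1L] != histories$first[i])
      stop("detection bookkeeping corrupt for individual ", i, call. = FALSE)
    s <- histories$species[i]
    juv_first <- histories$age_at_first[i] == "juvenile"
    for (k in seq_along(det)) {
      rel <- det[k]
      if (rel >= T) break                       # no release at final occasion
      age <- if (k == 1L && juv_first) "juv" else "ad"
      out[[s]][[age]]$R[rel] <- out[[s]][[age]]$R[rel] + 1L
      if (k < length(det)) {
        out[[s]][[age]]$m[rel, det[k + 1L] - 1L] <-
          out[[s]][[age]]$m[rel, det[k + 1L] - 1L] + 1L
      } else {
        out[[s]][[age]]$never[rel] <- out[[s]][[age]]$never[rel] + 1L
      }
    }
  }
  for (s in sp) out[[s]]$has_juv <- sum(out[[s]]$juv$R) > 0L
  structure(out, years = histories$years, class = "marray_set")
}

#' @export
print.marray_set <- function(x, ...) {
  yrs <- attr(x, "years")
  cat("m-array set:", length(x), "species,", length(yrs), "occasions\n")
  for (s in names(x)) {
    cat(sprintf("  %-28s releases juv %5d  ad %5d\n", s,
                sum(x[[s]]$juv$R), sum(x[[s]]$ad$R)))
  }
  invisible(x)
}

#' Species body-size traits from adult masses
#'
#' Mean adult body mass per species (grams), with a standardized copy
#' (mean 0, sample SD 1 across the supplied species).
#'
#' @param records a `capture_records` data frame.
#' @param species character vector of species to summarize (default: all in
#'   `records`).
#' @param MB optional named binary vector: 1 = migrant, 0 = resident,
#'   names = species codes. `NA` entries allowed and carried through.
#' @return a `data.frame` with columns `species`, `MB`, `BS` and `BS_z`.
#' @export
species_body_size <- function(records, species = NULL, MB = NULL) {
  species <- sort(species %||% unique(records$species))
  bs <- vapply(species, function(s) {
    m <- records$body_mass[records$species == s & records$age_code == "adult"]
    m <- m[!is.na(m)]
    if (length(m) == 0L)
      stop("no adult body masses for species ", s, call. = FALSE)
    mean(m)
  }, numeric(1))
  mb <- if (is.null(MB)) rep(NA_real_, length(species)) else as.numeric(MB[species])
  data.frame(species = species, MB = mb, BS = bs,
             BS_z = if (length(species) > 1L) zstd(bs, "body size") else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an m-array set to CSV files plus a JSON manifest
#'
#' One CSV per species-by-age m-array (rows = release occasions, columns =
#' first-recapture occasions, `never`, `R`) and a `manifest.json` with
#' release counts.
#'
#' @param marrays an `marray_set`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_marrays <- function(marrays, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(years = attr(marrays, "years"), species = list())
  for (s in names(marrays)) {
    for (age in c("juv", "ad")) {
      a <- marrays[[s]][[age]]
      df <- data.frame(release_occ = rownames(a$m), a$m,
                       never = a$never, R = a$R, check.names = FALSE)
      utils::write.csv(df, file.path(dir, paste0("marray_", s, "_", age, ".csv")),
                       row.names = FALSE)
    }
    manifest$species[[s]] <- list(releases_juv = sum(marrays[[s]]$juv$R),
                                  releases_ad = sum(marrays[[s]]$ad$R))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
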