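write_banding <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("read_captures keeps well-formed rows and drops broken ones", {
  f <- write_banding(data.frame(
    band_id = c("a", "b", "c"), species = "sp",
    date = c("2001-10-01", "2002-01-15", "2003-11-30"),
    age_code = c("juvenile", "adult", "unknown"), body_mass = c(10, 11, NA)))
  rec <- read_captures(f)
  expect_equal(nrow(rec), 3L)
  expect_s3_class(rec$date, "Date")
  expect_equal(attr(rec, "n_dropped"), 0L)

  f2 <- write_banding(data.frame(
    band_id = c("a", "b"), species = "sp",
    date = c("2001-13-40", "2002-01-15"), age_code = "adult", body_mass = 1))
  rec2 <- read_captures(f2)
  expect_equal(nrow(rec2), 1L)
  expect_equal(attr(rec2, "n_dropped"), 1L)
})

test_that("read_captures validates schema and rejects empty input", {
  f <- write_banding(data.frame(band_id = "a", species = "sp",
                                when = "2001-10-01", age_code = "adult"))
  expect_error(read_captures(f), "missing required column")
  f2 <- write_banding(data.frame(band_id = character(0), species = character(0),
                                 date = character(0), age_code = character(0)))
  expect_error(read_captures(f2), "empty")
  # schema remapping makes the same file readable
  rec <- read_captures(f, schema = list(date = "when"))
  expect_equal(nrow(rec), 1L)
})

test_that("collapse_to_annual labels a season by its starting year", {
  rec <- data.frame(
    band_id = "b1", species = "sp",
    date = as.Date(c("2001-10-05", "2002-02-10", "2003-11-01")),
    age_code = "adult", body_mass = NA_real_)
  h <- collapse_to_annual(rec, years = 2001:2003)
  expect_equal(unname(h$H[1, ]), c(1L, 0L, 1L))   # Feb 2002 is season 2001
  expect_equal(h$first, 1L)
  expect_equal(h$age_at_first, "adult")
})

test_that("out-of-season records are discarded and unknown age maps to adult", {
  rec <- data.frame(band_id = c("b1", "b2"), species = "sp",
                    date = as.Date(c("2001-06-15", "2001-10-02")),
                    age_code = c("adult", "unknown"), body_mass = NA_real_)
  h <- collapse_to_annual(rec, years = 2001:2003)
  expect_equal(nrow(h$H), 1L)                     # June-only bird emits nothing
  expect_equal(h$age_at_first, "adult")
  expect_error(collapse_to_annual(rec, season = integer(0)), "season")
})

test_that("a juvenile code anywhere in the first season wins", {
  rec <- data.frame(band_id = "b1", species = "sp",
                    date = as.Date(c("2001-10-01", "2001-12-01")),
                    age_code = c("unknown", "juvenile"), body_mass = NA_real_)
  h <- collapse_to_annual(rec, years = 2001:2002)
  expect_equal(h$age_at_first, "juvenile")
})

test_that("collapse_to_annual is idempotent on already-annual data", {
  set.seed(5)
  hist <- rand_histories(50, 6)
  # one mid-season record per detection
  idx <- which(hist$H == 1L, arr.ind = TRUE)
  rec <- data.frame(band_id = sprintf("i%04d", idx[, 1]),
                    species = "sp",
                    date = as.Date(sprintf("%d-10-15", hist$years[idx[, 2]])),
                    age_code = "adult", body_mass = NA_real_)
  h1 <- collapse_to_annual(rec, years = hist$years)
  ord <- order(rownames(h1$H))
  expect_equal(unname(h1$H[ord, ]), unname(hist$H))
})

test_that("filter_species applies inclusive individual-level thresholds", {
  mk <- function(n, n_recap, sp) {
    H <- matrix(0L, n, 3); H[, 1] <- 1L
    if (n_recap > 0) H[seq_len(n_recap), 2] <- 1L
    structure(list(H = H, species = rep(sp, n),
                   age_at_first = rep("adult", n),
                   first = rep(1L, n), years = 2001:2003),
              class = "annual_histories")
  }
  merge2 <- function(a, b) structure(list(
    H = rbind(a$H, b$H), species = c(a$species, b$species),
    age_at_first = c(a$age_at_first, b$age_at_first),
    first = c(a$first, b$first), years = a$years), class = "annual_histories")
  h <- merge2(mk(55, 3, "few_recaps"), mk(50, 4, "boundary"))
  expect_equal(filter_species(h), "boundary")
  # monotone: raising a threshold never adds a species
  for (mc in c(10, 50, 60)) for (mr in c(0, 4, 5)) {
    base <- filter_species(h, mc, mr)
    expect_true(all(filter_species(h, mc + 10, mr) %in% base))
    expect_true(all(filter_species(h, mc, mr + 1) %in% base))
  }
})

test_that("build_marrays counts the textbook example correctly", {
  H <- rbind(c(1L, 1L, 0L), c(1L, 0L, 1L), c(1L, 0L, 0L))
  hist <- structure(list(H = H, species = rep("sp", 3),
                         age_at_first = rep("adult", 3),
                         first = rep(1L, 3), years = 2001:2003),
                    class = "annual_histories")
  ma <- build_marrays(hist)
  a <- ma$sp$ad
  expect_equal(unname(a$m[1, ]), c(1L, 1L))
  expect_equal(unname(a$never[1]), 1L)
  expect_equal(unname(a$R[1]), 3L)
  # the bird recaptured at occasion 2 is re-released there and never seen again
  expect_equal(unname(a$never[2]), 1L)
  expect_false(ma$sp$has_juv)

  h1 <- structure(list(H = matrix(c(1L, rep(0L, 5)), 1), species = "sp",
                       age_at_first = "juvenile", first = 1L, years = 2001:2006),
                  class = "annual_histories")
  m1 <- build_marrays(h1)
  expect_equal(sum(m1$sp$juv$m), 0L)
  expect_equal(unname(m1$sp$juv$never[1]), 1L)
  expect_equal(sum(m1$sp$juv$R), 1L)
})

test_that("build_marrays matches a naive per-individual recount on random data", {
  hist <- rand_histories(1000, 8, seed = 99)
  ma <- build_marrays(hist)$sp
  oracle <- recount_marrays(hist)
  expect_equal(unname(ma$juv$m), oracle$juv$m)
  expect_equal(unname(ma$ad$m), oracle$ad$m)
  expect_equal(unname(ma$juv$never), oracle$juv$never)
  expect_equal(unname(ma$ad$never), oracle$ad$never)
  expect_equal(unname(ma$ad$R), oracle$ad$R)
  # row-sum conservation for every row of both arrays
  for (a in list(ma$juv, ma$ad))
    expect_equal(rowSums(a$m) + a$never, as.numeric(a$R),
                 ignore_attr = TRUE)
  # releases across both arrays = detections at occasions 1..T-1
  expect_equal(sum(ma$juv$R) + sum(ma$ad$R), sum(hist$H[, -ncol(hist$H)]))
})

test_that("species_body_size averages adult masses and standardizes", {
  rec <- data.frame(band_id = c("a", "a", "b"), species = "sp",
                    date = as.Date("2001-10-01"),
                    age_code = c("adult", "adult", "juvenile"),
                    body_mass = c(10, 12, 99))
  expect_equal(species_body_size(rec)$BS, 11)
  rec_j <- rec[rec$age_code == "juvenile", ]
  expect_error(species_body_size(rec_j), "no adult body masses")

  set.seed(2)
  recs <- do.call(rbind, lapply(1:5, function(i)
    data.frame(band_id = paste0(i, "_", 1:4), species = paste0("sp", i),
               date = as.Date("2001-10-01"), age_code = "adult",
               body_mass = rnorm(4, 10 * i, 1))))
  tr <- species_body_size(recs)
  # z-scores recomputed with the one-pass formula
  z <- (tr$BS - mean(tr$BS)) / sqrt(sum((tr$BS - mean(tr$BS))^2) / 4)
  expect_equal(tr$BS_z, z, tolerance = 1e-12)
  expect_equal(mean(tr$BS_z), 0, tolerance = 1e-12)
  expect_equal(sd(tr$BS_z), 1, tolerance = 1e-12)
})
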