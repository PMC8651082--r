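panel_mcr <- mcr_panel()

meta4 <- tibble::tibble(
  metagenome_id = c("m1", "m2", "m3", "m4"),
  ecosystem = c("environmental", "environmental", "host-associated",
                "engineered"),
  longitude = c(10.5, 10.5, 10.5, -80.25),
  latitude = c(45.1, 45.1, 45.1, 12.0),
  add_date = as.Date(c("2010-06-01", "2012-01-15", "2011-03-03",
                       "2015-09-30")),
  sample_date = as.Date(c("2010-05-01", "2011-12-01", "2010-05-01", NA)))

rows4 <- tibble::tibble(
  metagenome_id = c("m1", "m2", "m3", "m4"),
  McrA = c(1L, 0L, 0L, 1L),
  McrB = c(0L, 1L, 0L, 0L),
  McrG = c(0L, 0L, 0L, 1L))

test_that("detection history thresholds evidence counts at >= 1", {
  ev <- tibble::tibble(
    metagenome_id = c("m1", "m1", "m1", "m2"),
    marker = c("McrA", "McrG", "McrB", "McrA"),
    n_sequences = c(2L, 1L, 0L, 57L))
  h <- build_history(ev, panel_mcr, metagenomes = c("m1", "m2", "m3"))
  expect_equal(unlist(h[h$metagenome_id == "m1", panel_mcr$marker]),
               c(McrA = 1L, McrB = 0L, McrG = 1L))
  # 57 sequences is still just a detection
  expect_equal(h$McrA[h$metagenome_id == "m2"], 1L)
  # a metagenome with no surviving evidence is an all-zero row
  expect_equal(sum(unlist(h[h$metagenome_id == "m3", panel_mcr$marker])), 0L)
  expect_error(build_history(
    tibble::tibble(metagenome_id = "m", marker = "NotAMarker",
                   n_sequences = 1L), panel_mcr), "NotAMarker")
})

test_that("add dates convert to days since 2006-01-01", {
  expect_equal(numeric_add_date("2006-01-01"), 0L)
  expect_equal(numeric_add_date("2006-01-31"), 30L)
  expect_equal(numeric_add_date("2007-01-01"), 365L)
  expect_error(numeric_add_date("2005-12-31"), "epoch")
})

test_that("site aggregation ORs detections within the grouping key", {
  # same coordinates, two metagenomes -> one site with OR-ed history
  geo <- aggregate_sites(rows4, meta4, "geocoordinates")
  expect_equal(nrow(geo$history), 2)
  merged <- geo$history[geo$history$member_count == 3, ]
  expect_equal(unlist(merged[, c("McrA", "McrB", "McrG")]),
               c(McrA = 1L, McrB = 1L, McrG = 0L))
  # ecosystem is not a covariate of coordinate-only sites
  expect_false("ecosystem" %in% names(geo$sites))
  # earliest member add date carries over
  expect_equal(geo$sites$numeric_add_date[geo$history$member_count == 3],
               numeric_add_date("2010-06-01"))
  # the cow-rumen-vs-soil split: same coordinates, different ecosystem
  eco <- aggregate_sites(rows4, meta4, "geocoordinates_and_ecosystem")
  expect_equal(nrow(eco$history), 3)
  expect_true("ecosystem" %in% names(eco$sites))
  # scheme none is the identity
  none <- aggregate_sites(rows4, meta4, "none")
  expect_equal(nrow(none$history), 4)
  expect_equal(none$history$McrA, rows4$McrA)
  expect_error(aggregate_sites(rows4, meta4[-1, ], "none"), "m1")
})

test_that("aggregation is monotone and associative under OR", {
  set.seed(99)
  n <- 60
  meta <- tibble::tibble(
    metagenome_id = sprintf("g%02d", 1:n),
    ecosystem = sample(c("environmental", "engineered"), n, TRUE),
    longitude = sample(c("1.5", "2.5", "3.5"), n, TRUE),
    latitude = sample(c("40", "50"), n, TRUE),
    add_date = as.Date("2010-01-01") + sample(0:1000, n, TRUE),
    sample_date = as.Date("2010-01-01") + sample(0:1000, n, TRUE))
  rows <- tibble::tibble(
    metagenome_id = meta$metagenome_id,
    McrA = rbinom(n, 1, 0.3), McrB = rbinom(n, 1, 0.3),
    McrG = rbinom(n, 1, 0.3))
  agg <- aggregate_sites(rows, meta, "geocoordinates")
  expect_lte(nrow(agg$history), n)
  # every member's detection is dominated by its site's OR
  for (i in seq_len(nrow(agg$history))) {
    members <- strsplit(agg$history$member_ids[i], ";")[[1]]
    sub <- rows[rows$metagenome_id %in% members, c("McrA", "McrB", "McrG")]
    expect_equal(unlist(agg$history[i, c("McrA", "McrB", "McrG")]),
                 vapply(sub, function(x) as.integer(any(x == 1)),
                        integer(1)))
  }
  # aggregating the finer (coords + ecosystem) partition again by coords
  # gives the same OR as aggregating directly
  eco <- aggregate_sites(rows, meta, "geocoordinates_and_ecosystem")
  eco_rows <- eco$history |>
    dplyr::transmute(metagenome_id = .data$site_id, .data$McrA, .data$McrB,
                     .data$McrG)
  eco_meta <- tibble::tibble(
    metagenome_id = eco$history$site_id,
    ecosystem = NA_character_,
    longitude = eco$sites$longitude, latitude = eco$sites$latitude,
    add_date = as.Date("2006-01-01") + eco$sites$numeric_add_date)
  twice <- aggregate_sites(eco_rows, eco_meta, "geocoordinates")
  direct <- aggregate_sites(rows, meta, "geocoordinates")
  key <- function(h) h[order(h$site_id), c("McrA", "McrB", "McrG")]
  expect_equal(as.data.frame(key(twice$history)),
               as.data.frame(key(direct$history)),
               ignore_attr = TRUE)
})

test_that("mixed sample dates are flagged but never split sites", {
  agg <- aggregate_sites(rows4, meta4, "geocoordinates")
  expect_equal(attr(agg$sites, "n_mixed_dates"), 1L)
  expect_equal(sum(agg$sites$mixed_dates), 1L)
})

test_that("incomplete-site removal is listwise and idempotent", {
  sites <- tibble::tibble(
    site_id = sprintf("s%d", 1:5),
    ecosystem = c("environmental", NA, "engineered", "engineered",
                  "host-associated"),
    latitude = c(1, 2, NA, 4, 5),
    numeric_add_date = c(10L, 20L, 30L, 40L, 50L))
  hist <- tibble::tibble(site_id = sites$site_id, McrA = c(1L, 0L, 1L, 0L, 1L))
  out <- drop_incomplete(hist, sites, c("ecosystem", "latitude"))
  expect_equal(nrow(out$sites), 3)
  expect_equal(out$n_dropped, 2)
  expect_equal(out$history$site_id, out$sites$site_id)
  again <- drop_incomplete(out$history, out$sites, c("ecosystem", "latitude"))
  expect_equal(again$sites, out$sites)
  expect_equal(again$n_dropped, 0)
  # nothing missing -> identity
  full <- drop_incomplete(hist, sites, "numeric_add_date")
  expect_equal(full$sites, sites)
  expect_error(drop_incomplete(hist, sites, "no_such_covariate"),
               "no_such_covariate")
})

test_that("design matrices have deterministic columns and an intercept", {
  sites <- tibble::tibble(
    ecosystem = c("environmental", "engineered", "host-associated",
                  "environmental"),
    latitude = c(10, 20, 30, 40),
    numeric_add_date = c(100L, 400L, 900L, 1600L),
    sqrt_numeric_add_date = c(10, 20, 30, 40))
  expect_equal(colnames(design_matrix(sites, "1")), "(Intercept)")
  eco <- design_matrix(sites, "ecosystem")
  expect_equal(ncol(eco), 3)  # with p ~ 1 detection this is a 4-parameter model
  expect_equal(colnames(eco)[1], "(Intercept)")
  expect_equal(attr(eco, "ecosystem_levels"),
               c("engineered", "environmental", "host-associated"))
  both <- design_matrix(sites, "ecosystem + sqrt(numeric.add.date)")
  expect_equal(ncol(both), 4)
  expect_equal(both[, "sqrt(numeric.add.date)"],
               sites$sqrt_numeric_add_date)
  expect_error(design_matrix(sites, "pH"), "pH")
  expect_error(design_matrix(sites, "ecosystem",
                             ecosystem_levels = c("engineered",
                                                  "environmental")),
               "host-associated")
  # the special empty block
  expect_equal(ncol(design_matrix(sites, "0")), 0)
})

test_that("occupancy tables round-trip through write/read bit-exactly", {
  tab <- dplyr::left_join(rows4, meta4, by = "metagenome_id")
  path <- withr::local_tempfile(fileext = ".csv")
  write_occupancy_table(tab, path)
  back <- read_occupancy_table(path)
  expect_equal(as.data.frame(back[, names(tab)]), as.data.frame(tab))
  # header adaptation via col_map
  tab2 <- dplyr::rename(tab, taxon_oid = "metagenome_id")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_occupancy_table(tab2, path2)
  mapped <- read_occupancy_table(path2,
                                 col_map = c(metagenome_id = "taxon_oid"))
  expect_true("metagenome_id" %in% names(mapped))
  expect_error(read_occupancy_table(path2), "metagenome_id")
})
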