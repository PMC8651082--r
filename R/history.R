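#' Build per-metagenome detection histories from curated evidence
#'
#' A metagenome scores 1 for a marker when at least one curated sequence of
#' that marker survived, regardless of the total number of detections, and
#' 0 otherwise.
#'
#' @param evidence Tibble (`metagenome_id`, `marker`, `n_sequences`) as
#'   produced by [curate()].
#' @param panel A [marker_panel()]; its marker order fixes the survey order
#'   (columns) of the history.
#' @param metagenomes Optional character vector of all metagenome ids to
#'   report rows for (metagenomes with no curated evidence get all-zero
#'   rows). Defaults to the ids present in `evidence`.
#' @return Tibble with `metagenome_id` and one 0/1 column per marker.
#' @export
build_history <- function(evidence, panel,
                          metagenomes = unique(evidence$metagenome_id)) {
  evidence <- tibble::as_tibble(evidence)
  unknown <- setdiff(unique(evidence$marker), panel$marker)
  if (length(unknown)) {
    stop("unknown marker symbols in evidence: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(evidence$n_sequences >= 0))
  grid <- tidyr::expand_grid(metagenome_id = metagenomes,
                             marker = panel$marker)
  grid |>
    dplyr::left_join(evidence, by = c("metagenome_id", "marker")) |>
    dplyr::mutate(present = as.integer(!is.na(.data$n_sequences) &
                                         .data$n_sequences >= 1)) |>
    dplyr::select(-"n_sequences") |>
    tidyr::pivot_wider(names_from = "marker", values_from = "present") |>
    dplyr::select("metagenome_id", dplyr::all_of(panel$marker))
}

#' Days since 1 January 2006
#'
#' The numeric form of a database add date used as a detection covariate.
#'
#' @param date A `Date` or parseable date string.
#' @param epoch Epoch date mapped to 0.
#' @return Integer day count (epoch itself is day 0). Dates before the
#'   epoch are an error, not clamped.
#' @export
numeric_add_date <- function(date, epoch = as.Date("2006-01-01")) {
  date <- as.Date(date)
  d <- as.integer(date - as.Date(epoch))
  if (any(d < 0, na.rm = TRUE)) {
    stop("add date precedes the epoch ", format(as.Date(epoch)), ": ",
         paste(format(date[which(d < 0)]), collapse = ", "), call. = FALSE)
  }
  d
}

norm_coord <- function(x) {
  # textual normalization: trimmed, not rounded — numeric rounding would
  # silently merge distinct sites
  trimws(as.character(x))
}

#' Aggregate metagenome detection histories into sites
#'
#' Implements the three site definitions: each metagenome its own site
#' (`"none"`); metagenomes sharing identical geographic coordinates merged
#' into one site (`"geocoordinates"`), so soil cores and depth profiles
#' collapse; and additionally split by ecosystem category
#' (`"geocoordinates_and_ecosystem"`), since e.g. a cow rumen and the soil
#' of the same pasture do not interact. Within a site, detections are OR-ed:
#' any member metagenome encoding a marker codes that marker 1.
#'
#' Coordinates are grouped on their trimmed textual representation, exactly
#' as they appear in the metadata. Sample date is never part of the grouping
#' key; the returned site table carries a `mixed_dates` flag and the result
#' has an attribute `n_mixed_dates` counting aggregated sites whose members
#' span more than one sample date. The aggregated add date is the earliest
#' member date. Under `"geocoordinates"` the ecosystem covariate is not
#' emitted (members may disagree).
#'
#' @param rows Tibble with `metagenome_id` plus one 0/1 column per marker
#'   in `markers`.
#' @param metadata Tibble with `metagenome_id`, `ecosystem`, `longitude`,
#'   `latitude`, `add_date` and optionally `sample_date`. May be the same
#'   table as `rows`.
#' @param scheme One of `"none"`, `"geocoordinates"`,
#'   `"geocoordinates_and_ecosystem"`.
#' @param markers Character vector naming the detection columns of `rows`.
#' @return List with `history` (tibble: `site_id`, marker columns,
#'   `member_count`, `member_ids`) and `sites` (tibble: `site_id`,
#'   covariates incl. `numeric_add_date`, `sqrt_numeric_add_date`).
#' @export
aggregate_sites <- function(rows, metadata, scheme = c(
                              "none", "geocoordinates",
                              "geocoordinates_and_ecosystem"),
                            markers = setdiff(names(rows), "metagenome_id")) {
  scheme <- match.arg(scheme)
  rows <- tibble::as_tibble(rows)
  metadata <- tibble::as_tibble(metadata)
  orphans <- setdiff(rows$metagenome_id, metadata$metagenome_id)
  if (length(orphans)) {
    stop("metagenome ids missing from metadata: ",
         paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
  }
  meta_cols <- intersect(c("ecosystem", "longitude", "latitude",
                           "add_date", "sample_date"), names(metadata))
  dat <- dplyr::left_join(
    rows[, c("metagenome_id", markers)],
    metadata[, c("metagenome_id", meta_cols)],
    by = "metagenome_id")
  if (!"sample_date" %in% names(dat)) dat$sample_date <- NA

  if (scheme == "none") {
    history <- dat |>
      dplyr::transmute(site_id = .data$metagenome_id,
                       dplyr::across(dplyr::all_of(markers)),
                       member_count = 1L,
                       member_ids = .data$metagenome_id)
    sites <- dat |>
      dplyr::transmute(
        site_id = .data$metagenome_id,
        ecosystem = .data$ecosystem,
        longitude = .data$longitude,
        latitude = .data$latitude,
        numeric_add_date = ifelse(is.na(.data$add_date), NA_integer_,
                                  numeric_add_date(.data$add_date)),
        sqrt_numeric_add_date = sqrt(.data$numeric_add_date),
        mixed_dates = FALSE)
    attr(sites, "n_mixed_dates") <- 0L
    return(list(history = history, sites = sites))
  }

  dat <- dat |>
    dplyr::mutate(lon_key = norm_coord(.data$longitude),
                  lat_key = norm_coord(.data$latitude))
  keys <- c("lon_key", "lat_key")
  if (scheme == "geocoordinates_and_ecosystem") keys <- c(keys, "ecosystem")

  grouped <- dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(markers), ~ as.integer(any(.x == 1))),
      member_count = dplyr::n(),
      member_ids = paste(.data$metagenome_id, collapse = ";"),
      longitude = .data$longitude[1],
      latitude = .data$latitude[1],
      add_date = if (all(is.na(.data$add_date))) .data$add_date[1] else
        min(.data$add_date, na.rm = TRUE),
      mixed_dates = dplyr::n_distinct(.data$sample_date, na.rm = TRUE) > 1,
      .groups = "drop"
    )
  grouped$site_id <- do.call(paste, c(grouped[keys], sep = "_"))

  history <- grouped |>
    dplyr::select("site_id", dplyr::all_of(markers), "member_count",
                  "member_ids")
  sites <- grouped |>
    dplyr::transmute(
      site_id = .data$site_id,
      longitude = .data$longitude,
      latitude = .data$latitude,
      numeric_add_date = ifelse(is.na(.data$add_date), NA_integer_,
                                numeric_add_date(.data$add_date)),
      sqrt_numeric_add_date = sqrt(.data$numeric_add_date),
      mixed_dates = .data$mixed_dates)
  if (scheme == "geocoordinates_and_ecosystem") {
    sites <- dplyr::bind_cols(sites[, "site_id"],
                              ecosystem = grouped$ecosystem,
                              sites[, -1])
  }
  attr(sites, "n_mixed_dates") <- sum(grouped$mixed_dates)
  list(history = history, sites = sites)
}

#' Remove sites with missing required covariates
#'
#' Listwise removal (no imputation): a site missing any one of the named
#' covariates is dropped from both the detection history and the site
#' table. Idempotent.
#'
#' @param history,sites Paired outputs of [aggregate_sites()].
#' @param required Character vector of covariate column names in `sites`.
#' @return List (`history`, `sites`, `n_dropped`).
#' @export
drop_incomplete <- function(history, sites, required) {
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols)) {
    stop("required covariates not present in site table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok <- !Reduce(`|`, lapply(required, function(v) is.na(sites[[v]])),
                rep(FALSE, nrow(sites)))
  keep_ids <- sites$site_id[ok]
  list(history = history[history$site_id %in% keep_ids, ],
       sites = sites[ok, ],
       n_dropped = sum(!ok))
}

#' Build a numeric design matrix from covariate terms
#'
#' Term vocabulary: `1` (intercept only), `ecosystem`, `latitude`,
#' `sqrt(numeric.add.date)`, joined with `+`. The intercept column is
#' always present, except for the special term `0`, which yields an empty
#' (zero-column) block whose linear predictor is identically zero. The ecosystem factor is coded with treatment contrasts
#' against the lexicographically first level (`"engineered"` for the three
#' standard categories); likelihood and AIC are invariant to that choice.
#'
#' @param sites Site table with the referenced covariate columns.
#' @param terms Character scalar, e.g. `"ecosystem + sqrt(numeric.add.date)"`.
#' @param ecosystem_levels Optional fixed level set (used by prediction so
#'   that unseen levels error rather than silently re-code).
#' @return Numeric matrix with deterministic column order and an
#'   `ecosystem_levels` attribute when the ecosystem term is used.
#' @export
design_matrix <- function(sites, terms, ecosystem_levels = NULL) {
  parts <- trimws(strsplit(terms, "+", fixed = TRUE)[[1]])
  parts <- parts[parts != ""]
  if (length(parts) == 0) parts <- "1"
  n <- nrow(sites)
  if (identical(parts, "0")) {
    # empty block: the linear predictor is identically zero (used to pin
    # the two-species interaction at independence)
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(NULL, character(0))))
  }
  out <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  eco_levels <- NULL
  for (term in setdiff(parts, "1")) {
    if (term == "ecosystem") {
      x <- as.character(sites$ecosystem)
      if (is.null(ecosystem_levels)) {
        eco_levels <- sort(unique(x))
      } else {
        eco_levels <- ecosystem_levels
        unseen <- setdiff(x, eco_levels)
        if (length(unseen)) {
          stop("unseen ecosystem level(s): ",
               paste(unique(unseen), collapse = ", "), call. = FALSE)
        }
      }
      f <- factor(x, levels = eco_levels)
      for (lev in eco_levels[-1]) {
        out <- cbind(out, as.numeric(f == lev))
        colnames(out)[ncol(out)] <- paste0("ecosystem", lev)
      }
    } else if (term == "latitude") {
      out <- cbind(out, latitude = as.numeric(sites$latitude))
    } else if (term %in% c("sqrt(numeric.add.date)",
                           "sqrt(numeric_add_date)")) {
      v <- if ("sqrt_numeric_add_date" %in% names(sites)) {
        as.numeric(sites$sqrt_numeric_add_date)
      } else {
        sqrt(as.numeric(sites$numeric_add_date))
      }
      out <- cbind(out, `sqrt(numeric.add.date)` = v)
    } else {
      stop("unknown covariate term: '", term, "'", call. = FALSE)
    }
  }
  if (!is.null(eco_levels)) attr(out, "ecosystem_levels") <- eco_levels
  out
}

#' Read / write an occupancy-plus-metadata table
#'
#' The delimited dialect has one row per metagenome with columns
#' `metagenome_id`, the six marker columns (`McrA`, `McrB`, `McrG`, `PmoA`,
#' `PmoB`, `PmoC`), `ecosystem`, `longitude`, `latitude`, `add_date`,
#' `sample_date`. A `col_map` (named character vector, canonical name ->
#' file header) adapts other headers.
#'
#' @param path File path.
#' @param delim Field delimiter (comma default).
#' @param col_map Optional header mapping.
#' @return Tibble in canonical column names.
#' @export
read_occupancy_table <- function(path, delim = ",", col_map = NULL) {
  tab <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           progress = FALSE, show_col_types = FALSE)
  if (!is.null(col_map)) {
    for (canonical in names(col_map)) {
      if (!col_map[[canonical]] %in% names(tab)) {
        stop("mapped column '", col_map[[canonical]], "' not found in ",
             path, call. = FALSE)
      }
      names(tab)[names(tab) == col_map[[canonical]]] <- canonical
    }
  }
  if (!"metagenome_id" %in% names(tab)) {
    stop("occupancy table needs a 'metagenome_id' column (or a col_map ",
         "entry for it)", call. = FALSE)
  }
  tab$metagenome_id <- as.character(tab$metagenome_id)
  tab
}

#' @rdname read_occupancy_table
#' @param tab Table to write.
#' @export
write_occupancy_table <- function(tab, path, delim = ",") {
  readr::write_delim(tab, path, delim = delim)
  invisible(path)
}
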