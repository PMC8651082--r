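#' Simulation configuration
#'
#' Collects everything a simulated survey needs: site count, surveys per
#' site, true coefficient blocks on the logit / natural-parameter scale,
#' covariate generators, and a mandatory seed. Covariate defaults emulate
#' the global metagenome survey the package targets: ecosystem categories
#' drawn with probabilities 0.806 / 0.133 / 0.062
#' (environmental / host-associated / engineered) and latitude uniform on
#' [-60, 75]. Separate pseudo-random streams (sub-seeds) are used for
#' covariates, latent states and detections, so fixing `seed` fixes every
#' artifact.
#'
#' @param n_sites Number of sites.
#' @param K Surveys (markers) per site.
#' @param psi_terms,beta_psi Occupancy terms and true coefficients
#'   (single-species).
#' @param p_terms,alpha_p Detection terms and true coefficients.
#' @param f1_terms,beta_f1,f2_terms,beta_f2,f12_terms,beta_f12 Natural
#'   parameter terms and coefficients (two-species).
#' @param p1,p2 True detection probabilities (two-species).
#' @param ecosystem_probs Named category probabilities.
#' @param latitude_range,longitude_range Uniform covariate ranges.
#' @param add_date_range Day range (since 2006-01-01) for add dates.
#' @param seed Mandatory integer seed.
#' @return A `simulation_config` list, serializable with
#'   [jsonlite::toJSON()].
#' @export
simulation_config <- function(n_sites = 500, K = 3,
                              psi_terms = "1",
                              beta_psi = stats::qlogis(0.6),
                              p_terms = "1",
                              alpha_p = stats::qlogis(0.4),
                              f1_terms = "1", beta_f1 = 0,
                              f2_terms = "1", beta_f2 = 0,
                              f12_terms = "1", beta_f12 = 0,
                              p1 = 0.5, p2 = 0.5,
                              ecosystem_probs = c(
                                environmental = 0.806,
                                `host-associated` = 0.133,
                                engineered = 0.062),
                              latitude_range = c(-60, 75),
                              longitude_range = c(-180, 180),
                              add_date_range = c(0L, 4748L),
                              seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(n_sites >= 1, K >= 1, all(ecosystem_probs >= 0),
            sum(ecosystem_probs) > 0,
            p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  # category weights are normalized (published shares may round to > 100%)
  ecosystem_probs <- ecosystem_probs / sum(ecosystem_probs)
  structure(list(
    n_sites = as.integer(n_sites), K = as.integer(K),
    psi_terms = psi_terms, beta_psi = beta_psi,
    p_terms = p_terms, alpha_p = alpha_p,
    f1_terms = f1_terms, beta_f1 = beta_f1,
    f2_terms = f2_terms, beta_f2 = beta_f2,
    f12_terms = f12_terms, beta_f12 = beta_f12,
    p1 = p1, p2 = p2,
    ecosystem_probs = ecosystem_probs,
    latitude_range = latitude_range, longitude_range = longitude_range,
    add_date_range = as.integer(add_date_range),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

sim_covariates <- function(config) {
  set.seed(config$seed)
  n <- config$n_sites
  days <- sample(seq(config$add_date_range[1], config$add_date_range[2]),
                 n, replace = TRUE)
  tibble::tibble(
    site_id = sprintf("s%04d", seq_len(n)),
    ecosystem = sample(names(config$ecosystem_probs), n, replace = TRUE,
                       prob = config$ecosystem_probs),
    longitude = round(stats::runif(n, config$longitude_range[1],
                                   config$longitude_range[2]), 4),
    latitude = round(stats::runif(n, config$latitude_range[1],
                                  config$latitude_range[2]), 4),
    add_date = as.Date("2006-01-01") + days,
    sample_date = as.Date("2006-01-01") + pmax(0, days - 30),
    numeric_add_date = as.integer(days),
    sqrt_numeric_add_date = sqrt(days)
  )
}

#' Simulate a single-species occupancy survey
#'
#' Covariates are drawn first, site occupancy and detection probabilities
#' follow from the logit links, latent presence `z_i ~ Bernoulli(psi_i)`,
#' and detections `y_ik ~ Bernoulli(z_i * p_i)`.
#'
#' @param config A [simulation_config()].
#' @param markers Column names for the K surveys.
#' @return List: `history` (tibble `site_id` + marker columns), `sites`
#'   (covariate tibble), `truth` (latent states, per-site `psi`/`p`,
#'   config).
#' @export
simulate_single <- function(config,
                            markers = paste0("marker", seq_len(config$K))) {
  stopifnot(inherits(config, "simulation_config"), length(markers) == config$K)
  sites <- sim_covariates(config)
  X <- design_matrix(sites, config$psi_terms)
  W <- design_matrix(sites, config$p_terms)
  stopifnot(ncol(X) == length(config$beta_psi),
            ncol(W) == length(config$alpha_p))
  psi <- stats::plogis(drop(X %*% config$beta_psi))
  p <- stats::plogis(drop(W %*% config$alpha_p))
  n <- config$n_sites
  set.seed(config$seed + 1L)
  z <- stats::rbinom(n, 1, psi)
  set.seed(config$seed + 2L)
  Y <- matrix(stats::rbinom(n * config$K, 1, rep(z * p, config$K)),
              nrow = n, ncol = config$K)
  colnames(Y) <- markers
  history <- dplyr::bind_cols(sites[, "site_id"], tibble::as_tibble(Y))
  list(history = history, sites = sites,
       truth = list(z = z, psi = psi, p = p, config = config))
}

#' Simulate a paired two-species occupancy survey
#'
#' The joint latent state of each site is drawn from the multivariate
#' Bernoulli [state_probs()] at the site's natural parameters; detections
#' are then species-wise Bernoulli given presence.
#'
#' @param config A [simulation_config()].
#' @param markers1,markers2 Column names for each species' K surveys.
#' @return List: `history1`, `history2`, `sites`, `truth` (`z1`, `z2`,
#'   state probabilities, config).
#' @export
simulate_multi <- function(config,
                           markers1 = paste0("a", seq_len(config$K)),
                           markers2 = paste0("b", seq_len(config$K))) {
  stopifnot(inherits(config, "simulation_config"))
  sites <- sim_covariates(config)
  X1 <- design_matrix(sites, config$f1_terms)
  X2 <- design_matrix(sites, config$f2_terms)
  X12 <- design_matrix(sites, config$f12_terms)
  st <- state_probs(drop(X1 %*% config$beta_f1),
                    drop(X2 %*% config$beta_f2),
                    drop(X12 %*% config$beta_f12))
  n <- config$n_sites
  set.seed(config$seed + 1L)
  u <- stats::runif(n)
  cum <- t(apply(as.matrix(st), 1, cumsum))
  state <- 1L + rowSums(u > cum)          # 1..4: 00, 10, 01, 11
  z1 <- as.integer(state %in% c(2L, 4L))
  z2 <- as.integer(state %in% c(3L, 4L))
  set.seed(config$seed + 2L)
  Y1 <- matrix(stats::rbinom(n * config$K, 1, rep(z1 * config$p1, config$K)),
               nrow = n)
  Y2 <- matrix(stats::rbinom(n * config$K, 1, rep(z2 * config$p2, config$K)),
               nrow = n)
  colnames(Y1) <- markers1
  colnames(Y2) <- markers2
  list(history1 = dplyr::bind_cols(sites[, "site_id"], tibble::as_tibble(Y1)),
       history2 = dplyr::bind_cols(sites[, "site_id"], tibble::as_tibble(Y2)),
       sites = sites,
       truth = list(z1 = z1, z2 = z2, states = st, config = config))
}

random_aa <- function(n_res) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n_res,
               replace = TRUE), collapse = "")
}

#' Generate a deterministic curation test fixture
#'
#' Writes a small, fully synthetic marker-curation input set — candidate
#' FASTA, reference FASTA, label file, 12-column hit table, newick tree —
#' together with the ground-truth disposition ledger that [curate()] must
#' reproduce. The ~20 candidates cover every disposition reason at least
#' once: too short, too long, false-positive top hit, no hit, tree
#' false-positive neighbor, tree long branch, and clean.
#'
#' @param seed Integer seed (fixture is deterministic per seed).
#' @param dir Output directory (created if needed).
#' @return List of file paths plus `panel`, `refs`, `ledger` (expected
#'   dispositions) and `expected_evidence`.
#' @export
make_curation_fixtures <- function(seed = 1, dir = tempfile("curfix")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  panel <- marker_panel("MCR", "McrA", "K00399")

  refs <- tibble::tibble(
    id = c("ref_tp1", "ref_tp2", "ref_tp3", "ref_fp_anme"),
    marker = "McrA",
    label = c("true_positive", "true_positive", "true_positive",
              "false_positive"),
    length = c(550L, 560L, 580L, 555L))
  refs$sequence <- vapply(refs$length, random_aa, character(1))
  # window from true positives only: (500, 630)

  spec <- tibble::tribble(
    ~local, ~mg, ~len, ~reason,
    "c01", "mgA", 450L, "too_short",
    "c02", "mgA", 499L, "too_short",
    "c03", "mgB", 700L, "too_long",
    "c04", "mgB", 550L, "top_hit_false_positive",
    "c05", "mgC", 560L, "top_hit_false_positive",
    "c06", "mgC", 570L, "top_hit_false_positive",
    "c07", "mgD", 540L, "no_hit",
    "c08", "mgD", 545L, "no_hit",
    "c09", "mgE", 552L, "tree_fp_neighbor",
    "c10", "mgE", 558L, "tree_long_branch",
    "c11", "mgA", 551L, "clean",
    "c12", "mgA", 553L, "clean",
    "c13", "mgB", 555L, "clean",
    "c14", "mgB", 557L, "clean",
    "c15", "mgC", 559L, "clean",
    "c16", "mgC", 561L, "clean",
    "c17", "mgD", 563L, "clean",
    "c18", "mgE", 565L, "clean",
    "c19", "mgF", 567L, "clean",
    "c20", "mgF", 569L, "clean")
  spec$seq_id <- paste(spec$mg, "McrA", spec$local, sep = "|")
  spec$sequence <- vapply(spec$len, random_aa, character(1))

  # hit table: length survivors except the no-hit pair get hits
  hit_rows <- list()
  for (i in seq_len(nrow(spec))) {
    r <- spec$reason[i]
    q <- spec$seq_id[i]
    if (r %in% c("no_hit", "too_short", "too_long")) next
    if (r == "top_hit_false_positive") {
      subj <- if (spec$local[i] == "c04") "ref_fp_anme" else "bg_uniref_123"
      hit_rows[[length(hit_rows) + 1]] <-
        c(q, subj, "92.1", "500", "30", "2", "1", "500", "1", "500",
          "1e-150", "310")
      hit_rows[[length(hit_rows) + 1]] <-
        c(q, "ref_tp1", "88.0", "500", "45", "2", "1", "500", "1", "500",
          "1e-140", "250")
    } else {
      hit_rows[[length(hit_rows) + 1]] <-
        c(q, "ref_tp1", "95.0", "520", "20", "1", "1", "520", "1", "520",
          "1e-180", "200")
      hit_rows[[length(hit_rows) + 1]] <-
        c(q, "bg_uniref_456", "70.0", "480", "90", "4", "1", "480", "1",
          "480", "1e-90", "150")
    }
  }
  hits_path <- file.path(dir, "hits.tsv")
  writeLines(vapply(hit_rows, paste, character(1), collapse = "\t"),
             hits_path)

  # tree over stage-1/2 survivors + reference leaves; terminal branches are
  # short (0.03-0.08) except one 5.0 pendant, so median + 6*MAD flags it
  survivors <- spec$seq_id[spec$reason %in%
                             c("clean", "tree_fp_neighbor",
                               "tree_long_branch")]
  clean_ids <- spec$seq_id[spec$reason == "clean"]
  fp_q <- spec$seq_id[spec$reason == "tree_fp_neighbor"]
  lb_q <- spec$seq_id[spec$reason == "tree_long_branch"]
  quo <- function(x) paste0("'", x, "'")  # quoted labels keep the '|'
  clean_part <- paste(sprintf("%s:%.2f", quo(clean_ids),
                              seq(0.03, 0.08, length.out = length(clean_ids))),
                      collapse = ",")
  nwk <- sprintf(
    "((ref_tp1:0.05,ref_tp2:0.06,%s,%s:5.0):0.1,(ref_fp_anme:0.05,%s:0.03):0.5,ref_tp3:0.07);",
    clean_part, quo(lb_q), quo(fp_q))
  tree_path <- file.path(dir, "tree.nwk")
  writeLines(nwk, tree_path)

  cand_path <- file.path(dir, "candidates.faa")
  writeLines(paste0(">", spec$seq_id, "\n", spec$sequence), cand_path)
  ref_path <- file.path(dir, "references.faa")
  writeLines(paste0(">", refs$id, "\n", refs$sequence), ref_path)
  labels_path <- file.path(dir, "labels.csv")
  readr::write_csv(tibble::tibble(subject_id = refs$id, label = refs$label),
                   labels_path)

  ledger <- tibble::tibble(
    seq_id = spec$seq_id, metagenome_id = spec$mg, marker = "McrA",
    kept = spec$reason == "clean", reason = spec$reason)
  ledger_path <- file.path(dir, "expected_ledger.csv")
  readr::write_csv(ledger, ledger_path)

  expected_evidence <- ledger |>
    dplyr::filter(.data$kept) |>
    dplyr::count(.data$metagenome_id, .data$marker, name = "n_sequences")

  list(dir = dir, candidates = cand_path, references = ref_path,
       labels = labels_path, hits = hits_path, tree = tree_path,
       ledger_file = ledger_path, panel = panel, refs = refs,
       ledger = ledger, expected_evidence = expected_evidence)
}

#' Repeated simulate-and-refit parameter recovery
#'
#' Repeats [simulate_single()] + [occu()] under intercept-only truth and
#' reports per-parameter bias, RMSE and 95% Wald-interval coverage.
#' Replicates where the optimizer fails are recorded, not fatal.
#'
#' @param config Intercept-only [simulation_config()].
#' @param n_replicates Number of replicates (>= 1).
#' @param n_starts Optimizer starts per replicate (1 is enough for the
#'   well-behaved intercept-only likelihood and keeps experiments fast).
#' @return List: `summary` (tibble, one row per parameter with truth, mean
#'   estimate, bias, RMSE, coverage), `replicates` (per-replicate
#'   estimates), `n_failed`.
#' @export
recovery_experiment <- function(config, n_replicates = 100, n_starts = 1) {
  stopifnot(n_replicates >= 1,
            config$psi_terms == "1", config$p_terms == "1")
  psi_true <- stats::plogis(config$beta_psi)
  p_true <- stats::plogis(config$alpha_p)
  one <- function(r) {
    cfg <- config
    cfg$seed <- config$seed + 3L * r
    sim <- simulate_single(cfg)
    fit <- tryCatch(
      suppressWarnings(occu(sim$history, sim$sites, "p ~ 1, psi ~ 1",
                            n_starts = n_starts, seed = cfg$seed)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(replicate = r, converged = FALSE,
                            psi_hat = NA_real_, p_hat = NA_real_,
                            psi_lower = NA_real_, psi_upper = NA_real_,
                            p_lower = NA_real_, p_upper = NA_real_))
    }
    se <- sqrt(pmax(0, diag(fit$vcov)))
    tibble::tibble(
      replicate = r, converged = fit$convergence,
      psi_hat = stats::plogis(fit$coef[[1]]),
      p_hat = stats::plogis(fit$coef[[2]]),
      psi_lower = stats::plogis(fit$coef[[1]] - 1.96 * se[[1]]),
      psi_upper = stats::plogis(fit$coef[[1]] + 1.96 * se[[1]]),
      p_lower = stats::plogis(fit$coef[[2]] - 1.96 * se[[2]]),
      p_upper = stats::plogis(fit$coef[[2]] + 1.96 * se[[2]]))
  }
  reps <- purrr::map_dfr(seq_len(n_replicates), one)
  ok <- reps[!is.na(reps$psi_hat), ]
  summarise_par <- function(par, truth) {
    est <- ok[[paste0(par, "_hat")]]
    tibble::tibble(
      parameter = par, truth = truth,
      mean_estimate = mean(est), bias = mean(est) - truth,
      rmse = sqrt(mean((est - truth)^2)),
      coverage = mean(ok[[paste0(par, "_lower")]] <= truth &
                        truth <= ok[[paste0(par, "_upper")]]),
      n_used = nrow(ok))
  }
  list(summary = dplyr::bind_rows(summarise_par("psi", psi_true),
                                  summarise_par("p", p_true)),
       replicates = reps,
       n_failed = sum(is.na(reps$psi_hat)))
}
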