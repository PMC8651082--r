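#' Log-likelihood of one site's detection history
#'
#' The single-season, single-species occupancy likelihood for one site
#' surveyed K times with constant detection probability. With at least one
#' detection the site must be occupied: `psi * p^s * (1-p)^(K-s)` for `s`
#' detections. An all-zero history marginalizes over the latent state:
#' occupied-but-missed plus genuinely unoccupied,
#' `psi * (1-p)^K + (1-psi)`.
#'
#' @param y 0/1 detection vector of length K.
#' @param psi Occupancy probability in (0,1) (the boundary values 0/1 are
#'   accepted for degenerate checks).
#' @param p Detection probability, likewise.
#' @return The log-probability of the history.
#' @examples
#' site_log_likelihood(c(1, 0, 1), 0.5, 0.5)  # log(0.0625)
#' site_log_likelihood(c(0, 0, 0), 0.5, 0.5)  # log(0.5625)
#' @export
site_log_likelihood <- function(y, psi, p) {
  if (!all(y %in% c(0, 1))) {
    stop("detection history must be 0/1", call. = FALSE)
  }
  stopifnot(psi >= 0, psi <= 1, p >= 0, p <= 1)
  s <- sum(y)
  K <- length(y)
  if (s > 0) {
    log(psi) + s * log(p) + (K - s) * log1p(-p)
  } else {
    log(psi * (1 - p)^K + (1 - psi))
  }
}

# vectorized negative log-likelihood over sites; s = detections, K = surveys
occu_nll <- function(theta, X, W, s, K) {
  q <- ncol(X)
  eta_psi <- drop(X %*% theta[seq_len(q)])
  eta_p <- drop(W %*% theta[-seq_len(q)])
  psi <- stats::plogis(eta_psi)
  p <- stats::plogis(eta_p)
  det <- s > 0
  ll <- numeric(length(s))
  # detected sites: log psi + s log p + (K-s) log(1-p)
  ll[det] <- stats::plogis(eta_psi[det], log.p = TRUE) +
    s[det] * stats::plogis(eta_p[det], log.p = TRUE) +
    (K - s[det]) * stats::plogis(-eta_p[det], log.p = TRUE)
  # all-zero sites: log(psi (1-p)^K + 1 - psi)
  miss <- !det
  ll[miss] <- log(psi[miss] * (1 - p[miss])^K + (1 - psi[miss]))
  -sum(ll)
}

check_full_rank <- function(M, label) {
  qr_M <- qr(M)
  if (qr_M$rank < ncol(M)) {
    dropped <- colnames(M)[qr_M$pivot[(qr_M$rank + 1):ncol(M)]]
    stop("rank-deficient ", label, " design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

history_matrix <- function(history) {
  if (is.matrix(history)) {
    Y <- history
    if (is.null(rownames(Y))) rownames(Y) <- as.character(seq_len(nrow(Y)))
    return(Y)
  }
  history <- tibble::as_tibble(history)
  marker_cols <- setdiff(names(history),
                         c("site_id", "metagenome_id", "member_count",
                           "member_ids"))
  id_col <- intersect(c("site_id", "metagenome_id"), names(history))[1]
  Y <- as.matrix(history[, marker_cols])
  storage.mode(Y) <- "double"
  rownames(Y) <- if (!is.na(id_col)) as.character(history[[id_col]]) else
    as.character(seq_len(nrow(Y)))
  Y
}

#' Fit a single-species occupancy model by maximum likelihood
#'
#' Occupancy and detection probabilities are logit-linked linear functions
#' of site covariates, fitted jointly by quasi-Newton (BFGS) optimization
#' from multiple starting points (the zero vector plus seeded random
#' perturbations); the best log-likelihood wins. Standard errors come from
#' the inverse observed information (numerical Hessian at the optimum),
#' falling back to a pseudo-inverse with a warning when near-singular.
#'
#' @param history Detection history: a tibble from [aggregate_sites()] /
#'   [build_history()] (0/1 marker columns) or a 0/1 matrix, one row per
#'   site, one column per replicate survey.
#' @param sites Site covariate table (needed for non-intercept terms).
#' @param spec Model specification string, e.g. `"p ~ 1, psi ~ ecosystem"`
#'   (see [parse_occu_spec()]).
#' @param n_starts Number of optimizer starts (default 5).
#' @param seed Seed for the start perturbations (recorded in the fit).
#' @param maxit Maximum BFGS iterations per start.
#' @return An `occu_fit`: coefficients (blocks `psi_*`, `p_*` on the logit
#'   scale), covariance, log-likelihood, AIC, convergence and boundary
#'   flags. Non-identifiable cases (K = 1, or a species never detected)
#'   carry warnings in `$flags`.
#' @export
occu <- function(history, sites = NULL, spec = "p ~ 1, psi ~ 1",
                 n_starts = 5, seed = 1, maxit = 500) {
  terms <- parse_occu_spec(spec)
  Y <- history_matrix(history)
  if (!all(Y %in% c(0, 1))) stop("detection history must be 0/1",
                                 call. = FALSE)
  n <- nrow(Y)
  K <- ncol(Y)
  if (n < 1) stop("need at least one site", call. = FALSE)
  if (is.null(sites)) sites <- tibble::tibble(.rows = n)
  X <- design_matrix(sites, terms$psi_terms)
  W <- design_matrix(sites, terms$p_terms)
  check_full_rank(X, "occupancy")
  check_full_rank(W, "detection")
  s <- rowSums(Y)

  flags <- character()
  if (K == 1) {
    flags <- c(flags, "K=1: only the product psi*p is identifiable")
    warning("K = 1 survey: only the product psi*p is identifiable",
            call. = FALSE)
  }
  if (all(s == 0)) {
    flags <- c(flags, "species never detected: parameters not identifiable")
    warning("species never detected at any site; estimates are not ",
            "identifiable", call. = FALSE)
  }

  n_par <- ncol(X) + ncol(W)
  starts <- list(rep(0, n_par))
  if (n_starts > 1) {
    rs <- local({set.seed(seed)
      lapply(seq_len(n_starts - 1), function(i) stats::rnorm(n_par, 0, 1))})
    starts <- c(starts, rs)
  }

  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(st, occu_nll, X = X, W = W, s = s, K = K,
                            method = "BFGS",
                            control = list(maxit = maxit)), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  if (best$convergence != 0) {
    warning("optimizer did not report convergence (code ",
            best$convergence, ")", call. = FALSE)
  }

  theta <- best$par
  names(theta) <- c(paste0("psi_", colnames(X)), paste0("p_", colnames(W)))
  H <- try(stats::optimHess(theta, occu_nll, X = X, W = W, s = s, K = K),
           silent = TRUE)
  vc <- matrix(NA_real_, n_par, n_par)
  if (!inherits(H, "try-error")) {
    vc_try <- try(solve(H), silent = TRUE)
    if (inherits(vc_try, "try-error") ||
        any(!is.finite(diag(vc_try))) || any(diag(vc_try) < 0)) {
      warning("observed information near-singular; using pseudo-inverse",
              call. = FALSE)
      vc <- MASS::ginv(H)
    } else {
      vc <- vc_try
    }
  }
  dimnames(vc) <- list(names(theta), names(theta))

  psi_hat <- stats::plogis(drop(X %*% theta[seq_len(ncol(X))]))
  p_hat <- stats::plogis(drop(W %*% theta[-seq_len(ncol(X))]))
  boundary <- any(pmin(psi_hat, 1 - psi_hat) < 1e-6) ||
    any(pmin(p_hat, 1 - p_hat) < 1e-6)

  ll <- -best$value
  structure(list(
    coef = theta, vcov = vc, loglik = ll, n_params = n_par,
    aic = -2 * ll + 2 * n_par,
    convergence = best$convergence == 0,
    boundary = boundary, flags = flags,
    spec = terms, model = render_occu_spec(terms),
    psi_cols = colnames(X), p_cols = colnames(W),
    ecosystem_levels = attr(X, "ecosystem_levels") %||%
      attr(W, "ecosystem_levels"),
    n_sites = n, K = K, seed = seed, n_starts = n_starts
  ), class = "occu_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.occu_fit <- function(x, ...) {
  cat("<occu_fit> ", x$model, "\n", sep = "")
  cat(sprintf("  sites: %d  surveys: %d  logLik: %.3f  AIC: %.2f\n",
              x$n_sites, x$K, x$loglik, x$aic))
  if (x$boundary) cat("  note: estimate at/near parameter boundary\n")
  for (f in x$flags) cat("  warning: ", f, "\n", sep = "")
  print(round(x$coef, 4))
  invisible(x)
}

#' Naive occupancy estimate
#'
#' The fraction of sites with at least one detection. Under imperfect
#' detection (p < 1) its expectation is `psi * (1 - (1-p)^K)`, an
#' underestimate of psi.
#'
#' @param history Detection history (tibble or 0/1 matrix).
#' @return A proportion in `[0, 1]`.
#' @export
naive_occupancy <- function(history) {
  Y <- history_matrix(history)
  mean(rowSums(Y) > 0)
}

#' AIC model comparison table
#'
#' @param ... `occu_fit` / `occu_multi_fit` objects, or a single list of
#'   them.
#' @return Tibble (`model`, `n_params`, `AIC`, `delta_AIC`) sorted by
#'   ascending AIC; ties keep their input order.
#' @export
delta_aic <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], c("occu_fit", "occu_multi_fit"))) {
    fits <- fits[[1]]
  }
  tab <- purrr::map_dfr(fits, function(f) tibble::tibble(
    model = f$model, n_params = f$n_params, AIC = f$aic))
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  tab[order(tab$AIC), ]
}

predict_linear <- function(fit, newdata, which = c("psi", "p")) {
  which <- match.arg(which)
  terms <- if (which == "psi") fit$spec$psi_terms else fit$spec$p_terms
  X <- design_matrix(newdata, terms, ecosystem_levels = fit$ecosystem_levels)
  idx <- if (which == "psi") seq_along(fit$psi_cols) else
    length(fit$psi_cols) + seq_along(fit$p_cols)
  beta <- fit$coef[idx]
  vc <- fit$vcov[idx, idx, drop = FALSE]
  eta <- drop(X %*% beta)
  se <- sqrt(pmax(0, rowSums((X %*% vc) * X)))
  list(eta = eta, se = se)
}

#' Predict occupancy (or detection) probabilities with 95% intervals
#'
#' Point estimates are the inverse-logit of the linear predictor; intervals
#' are Wald intervals on the linear predictor mapped through the inverse
#' logit (delta method on the link scale), so they always lie inside (0,1)
#' and contain the estimate.
#'
#' @param fit An `occu_fit`.
#' @param newdata Site table with the covariates the fit used.
#' @return Tibble (`estimate`, `lower`, `upper`).
#' @export
predict_occupancy <- function(fit, newdata) {
  lp <- predict_linear(fit, newdata, "psi")
  tibble::tibble(estimate = stats::plogis(lp$eta),
                 lower = stats::plogis(lp$eta - 1.96 * lp$se),
                 upper = stats::plogis(lp$eta + 1.96 * lp$se))
}

#' @rdname predict_occupancy
#' @export
predict_detection <- function(fit, newdata) {
  lp <- predict_linear(fit, newdata, "p")
  tibble::tibble(estimate = stats::plogis(lp$eta),
                 lower = stats::plogis(lp$eta - 1.96 * lp$se),
                 upper = stats::plogis(lp$eta + 1.96 * lp$se))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an occupancy fit into a coefficient table
#'
#' @param x An `occu_fit`.
#' @param ... Unused.
#' @return Tibble (`component`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`), logit scale.
#' @method tidy occu_fit
#' @export
tidy.occu_fit <- function(x, ...) {
  se <- sqrt(pmax(0, diag(x$vcov)))
  comp <- c(rep("psi", length(x$psi_cols)), rep("p", length(x$p_cols)))
  term <- c(x$psi_cols, x$p_cols)
  z <- x$coef / se
  tibble::tibble(component = comp, term = term,
                 estimate = unname(x$coef), std.error = unname(se),
                 statistic = unname(z),
                 p.value = unname(2 * stats::pnorm(-abs(z))))
}

#' @method glance occu_fit
#' @export
glance.occu_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, n_params = x$n_params,
                 n_sites = x$n_sites, K = x$K,
                 converged = x$convergence, boundary = x$boundary)
}

#' Coefficient plot for an occupancy fit
#'
#' @param object An `occu_fit`.
#' @param ... Unused.
#' @return A ggplot: logit-scale estimates with 95% Wald intervals,
#'   faceted by model component.
#' @method autoplot occu_fit
#' @export
autoplot.occu_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error), height = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~ .data$component, scales = "free_y") +
    ggplot2::labs(x = "estimate (logit scale)", y = NULL,
                  title = object$model)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
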