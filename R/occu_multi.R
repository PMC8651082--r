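#' Joint occupancy-state probabilities of the two-species model
#'
#' The multivariate Bernoulli parameterization: the four latent states
#' (absent/absent, 1 only, 2 only, both) get unnormalized log-weights
#' `0, f1, f2, f1 + f2 + f12`, normalized by softmax (with max-subtraction
#' for overflow safety). `f12 = 0` factorizes into independent species;
#' `f12 > 0` means positive co-occurrence.
#'
#' @param f1,f2,f12 Natural parameters (scalars or equal-length vectors).
#' @return Tibble (`psi00`, `psi10`, `psi01`, `psi11`), rows summing to 1.
#' @examples
#' state_probs(0, 0, log(3))  # (1/6, 1/6, 1/6, 1/2)
#' @export
state_probs <- function(f1, f2, f12) {
  stopifnot(all(is.finite(f1)), all(is.finite(f2)), all(is.finite(f12)))
  lw <- cbind(0, f1, f2, f1 + f2 + f12)
  dimnames(lw) <- NULL
  lw <- lw - apply(lw, 1, max)
  w <- exp(lw)
  w <- w / rowSums(w)
  tibble::tibble(psi00 = w[, 1], psi10 = w[, 2],
                 psi01 = w[, 3], psi11 = w[, 4])
}

as_state_vec <- function(states) {
  if (is.data.frame(states)) {
    stopifnot(nrow(states) == 1)
    states <- unlist(states[1, c("psi00", "psi10", "psi01", "psi11")])
  }
  stopifnot(length(states) == 4, abs(sum(states) - 1) < 1e-8)
  states
}

#' Log-likelihood of one site's paired detection histories
#'
#' Marginalizes the product detection likelihood over the four joint latent
#' states: a species absent from the site contributes an indicator that it
#' was never detected; a species present contributes
#' `p^s (1-p)^(K-s)`.
#'
#' @param y1,y2 0/1 detection vectors (lengths may differ per species).
#' @param states A [state_probs()] row or numeric vector
#'   `(psi00, psi10, psi01, psi11)`.
#' @param p1,p2 Species-specific detection probabilities.
#' @return Log-probability of the pair of histories.
#' @export
multi_site_log_likelihood <- function(y1, y2, states, p1, p2) {
  if (!all(c(y1, y2) %in% c(0, 1))) {
    stop("detection histories must be 0/1", call. = FALSE)
  }
  st <- as_state_vec(states)
  s1 <- sum(y1); K1 <- length(y1)
  s2 <- sum(y2); K2 <- length(y2)
  L1 <- p1^s1 * (1 - p1)^(K1 - s1)   # detection likelihood if present
  L2 <- p2^s2 * (1 - p2)^(K2 - s2)
  I1 <- as.numeric(s1 == 0)          # only consistent state if absent
  I2 <- as.numeric(s2 == 0)
  unname(log(st[1] * I1 * I2 + st[2] * L1 * I2 + st[3] * I1 * L2 +
               st[4] * L1 * L2))
}

multi_nll <- function(theta, X1, X2, X12, s1, s2, K1, K2) {
  q1 <- ncol(X1); q2 <- ncol(X2); q12 <- ncol(X12)
  b1 <- theta[seq_len(q1)]
  b2 <- theta[q1 + seq_len(q2)]
  b12 <- theta[q1 + q2 + seq_len(q12)]
  p1 <- stats::plogis(theta[q1 + q2 + q12 + 1])
  p2 <- stats::plogis(theta[q1 + q2 + q12 + 2])
  f1 <- drop(X1 %*% b1); f2 <- drop(X2 %*% b2); f12 <- drop(X12 %*% b12)
  lw <- cbind(0, f1, f2, f1 + f2 + f12)
  dimnames(lw) <- NULL
  lw <- lw - apply(lw, 1, max)
  w <- exp(lw); w <- w / rowSums(w)
  L1 <- p1^s1 * (1 - p1)^(K1 - s1)
  L2 <- p2^s2 * (1 - p2)^(K2 - s2)
  I1 <- as.numeric(s1 == 0); I2 <- as.numeric(s2 == 0)
  lik <- w[, 1] * I1 * I2 + w[, 2] * L1 * I2 + w[, 3] * I1 * L2 +
    w[, 4] * L1 * L2
  -sum(log(pmax(lik, 1e-300)))
}

#' Fit the two-species occupancy model
#'
#' Joint maximum likelihood over the natural-parameter blocks (species 1,
#' species 2, interaction) and the two intercept-only detection
#' probabilities, by multi-start BFGS. Parameter count is
#' `|f1| + |f2| + |f12| + 2`.
#'
#' @param history1,history2 Detection histories of the two species over the
#'   same sites, in the same site order.
#' @param sites Site covariate table.
#' @param spec Specification string (see [parse_multi_spec()]) or term
#'   list.
#' @param species Optional species names for `psi[name]` notation.
#' @param n_starts,seed,maxit Optimizer controls as in [occu()].
#' @return An `occu_multi_fit` with coefficient blocks `f1_*`, `f2_*`,
#'   `f12_*`, `p1`, `p2`, covariance, log-likelihood and AIC. A
#'   quasi-separation flag is raised when any interaction coefficient
#'   exceeds 10 in absolute value.
#' @export
occu_multi <- function(history1, history2, sites = NULL,
                       spec = "psi[1] ~ 1, psi[2] ~ 1, psi[12] ~ 1",
                       species = NULL, n_starts = 5, seed = 1,
                       maxit = 1000) {
  terms <- parse_multi_spec(spec, species = species)
  Y1 <- history_matrix(history1)
  Y2 <- history_matrix(history2)
  if (nrow(Y1) != nrow(Y2)) {
    stop("the two detection histories must cover the same sites",
         call. = FALSE)
  }
  n <- nrow(Y1)
  if (is.null(sites)) sites <- tibble::tibble(.rows = n)
  X1 <- design_matrix(sites, terms$f1_terms)
  X2 <- design_matrix(sites, terms$f2_terms)
  X12 <- design_matrix(sites, terms$f12_terms)
  check_full_rank(X1, "psi[1]")
  check_full_rank(X2, "psi[2]")
  check_full_rank(X12, "psi[12]")
  s1 <- rowSums(Y1); s2 <- rowSums(Y2)
  K1 <- ncol(Y1); K2 <- ncol(Y2)
  n_par <- ncol(X1) + ncol(X2) + ncol(X12) + 2

  starts <- list(rep(0, n_par))
  if (n_starts > 1) {
    rs <- local({set.seed(seed)
      lapply(seq_len(n_starts - 1), function(i) stats::rnorm(n_par, 0, 1))})
    starts <- c(starts, rs)
  }
  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(st, multi_nll, X1 = X1, X2 = X2, X12 = X12,
                            s1 = s1, s2 = s2, K1 = K1, K2 = K2,
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
  block_names <- function(prefix, M) {
    if (ncol(M) == 0) character(0) else paste0(prefix, colnames(M))
  }
  names(theta) <- c(block_names("f1_", X1), block_names("f2_", X2),
                    block_names("f12_", X12), "p1", "p2")
  H <- try(stats::optimHess(theta, multi_nll, X1 = X1, X2 = X2, X12 = X12,
                            s1 = s1, s2 = s2, K1 = K1, K2 = K2),
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

  f12_idx <- grepl("^f12_", names(theta))
  flags <- character()
  if (any(abs(theta[f12_idx]) > 10)) {
    flags <- c(flags, "possible quasi-separation: |f12 coefficient| > 10")
  }
  ll <- -best$value
  structure(list(
    coef = theta, vcov = vc, loglik = ll, n_params = n_par,
    aic = -2 * ll + 2 * n_par,
    convergence = best$convergence == 0, flags = flags,
    spec = terms, model = render_multi_spec(terms), species = species,
    f1_cols = colnames(X1), f2_cols = colnames(X2),
    f12_cols = colnames(X12),
    ecosystem_levels = attr(X1, "ecosystem_levels") %||%
      attr(X2, "ecosystem_levels") %||% attr(X12, "ecosystem_levels"),
    n_sites = n, K1 = K1, K2 = K2, seed = seed, n_starts = n_starts
  ), class = "occu_multi_fit")
}

#' @export
print.occu_multi_fit <- function(x, ...) {
  cat("<occu_multi_fit> ", x$model, "\n", sep = "")
  cat(sprintf("  sites: %d  logLik: %.3f  AIC: %.2f  params: %d\n",
              x$n_sites, x$loglik, x$aic, x$n_params))
  for (f in x$flags) cat("  warning: ", f, "\n", sep = "")
  print(round(x$coef, 4))
  invisible(x)
}

#' @method tidy occu_multi_fit
#' @export
tidy.occu_multi_fit <- function(x, ...) {
  se <- sqrt(pmax(0, diag(x$vcov)))
  comp <- c(rep("f1", length(x$f1_cols)), rep("f2", length(x$f2_cols)),
            rep("f12", length(x$f12_cols)), "p1", "p2")
  term <- c(x$f1_cols, x$f2_cols, x$f12_cols, "(Intercept)", "(Intercept)")
  z <- x$coef / se
  tibble::tibble(component = comp, term = term,
                 estimate = unname(x$coef), std.error = unname(se),
                 statistic = unname(z),
                 p.value = unname(2 * stats::pnorm(-abs(z))))
}

#' @method glance occu_multi_fit
#' @export
glance.occu_multi_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, n_params = x$n_params,
                 n_sites = x$n_sites, converged = x$convergence)
}

#' Conditional occupancy from joint state probabilities
#'
#' `P(z_target = 1 | z_other = given)`: the probability one function is
#' present given the presence or absence of the other, e.g.
#' `psi11 / (psi11 + psi01)` for species 1 given species 2 present.
#'
#' @param states A [state_probs()] row or numeric 4-vector.
#' @param target Which species (1 or 2).
#' @param given_present Condition on the other species being present
#'   (`TRUE`) or absent (`FALSE`).
#' @return A probability.
#' @export
conditional_occupancy <- function(states, target = 1, given_present = TRUE) {
  st <- as_state_vec(states)
  num_den <- if (target == 1) {
    if (given_present) c(st[4], st[4] + st[3]) else c(st[2], st[2] + st[1])
  } else {
    if (given_present) c(st[4], st[4] + st[2]) else c(st[3], st[3] + st[1])
  }
  if (num_den[2] < 1e-12) {
    stop("conditioning event has probability < 1e-12", call. = FALSE)
  }
  unname(num_den[1] / num_den[2])
}

multi_states_at <- function(fit, newdata, theta = fit$coef) {
  q1 <- length(fit$f1_cols); q2 <- length(fit$f2_cols)
  q12 <- length(fit$f12_cols)
  X1 <- design_matrix(newdata, fit$spec$f1_terms,
                      ecosystem_levels = fit$ecosystem_levels)
  X2 <- design_matrix(newdata, fit$spec$f2_terms,
                      ecosystem_levels = fit$ecosystem_levels)
  X12 <- design_matrix(newdata, fit$spec$f12_terms,
                       ecosystem_levels = fit$ecosystem_levels)
  state_probs(drop(X1 %*% theta[seq_len(q1)]),
              drop(X2 %*% theta[q1 + seq_len(q2)]),
              drop(X12 %*% theta[q1 + q2 + seq_len(q12)]))
}

cond_at <- function(states, target) {
  tibble::tibble(
    row = rep(seq_len(nrow(states)), 2),
    condition = rep(c("present", "absent"), each = nrow(states)),
    estimate = c(
      vapply(seq_len(nrow(states)), function(i)
        conditional_occupancy(states[i, ], target, TRUE), numeric(1)),
      vapply(seq_len(nrow(states)), function(i)
        conditional_occupancy(states[i, ], target, FALSE), numeric(1))))
}

#' Conditional-occupancy curves over a covariate grid
#'
#' For each grid row, the probability that `target` is present given the
#' other function present vs absent, with 95% intervals by parametric
#' bootstrap (draws from the multivariate normal approximation of the
#' coefficients; default) or by the delta method. The bootstrap is
#' preferred because conditional occupancy is a ratio of sums of
#' transformed Gaussians and the delta approximation can misbehave near
#' boundaries.
#'
#' @param fit An `occu_multi_fit`.
#' @param newdata Covariate grid (tibble).
#' @param target Species index (1 or 2).
#' @param n_boot Bootstrap draws (0 omits intervals).
#' @param method `"bootstrap"` or `"delta"`.
#' @param seed Seed for the bootstrap draws.
#' @return `newdata` repeated for conditions `present`/`absent`, with
#'   `estimate` and (unless `n_boot = 0` under bootstrap) `lower`, `upper`.
#' @export
predict_conditional_curves <- function(fit, newdata, target = 1,
                                       n_boot = 1000,
                                       method = c("bootstrap", "delta"),
                                       seed = 1) {
  method <- match.arg(method)
  newdata <- tibble::as_tibble(newdata)
  est <- cond_at(multi_states_at(fit, newdata), target)
  out <- dplyr::bind_cols(newdata[est$row, , drop = FALSE],
                          est[, c("condition", "estimate")])
  if (method == "bootstrap" && n_boot == 0) return(out)

  if (method == "bootstrap") {
    set.seed(seed)
    draws <- MASS::mvrnorm(n_boot, fit$coef, fit$vcov)
    boot <- vapply(seq_len(n_boot), function(b) {
      cond_at(multi_states_at(fit, newdata, theta = draws[b, ]),
              target)$estimate
    }, numeric(nrow(est)))
    qs <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
    out$lower <- qs[1, ]
    out$upper <- qs[2, ]
  } else {
    # delta method: numerical gradient of each conditional probability
    # with respect to the full coefficient vector
    eps <- 1e-5
    base <- est$estimate
    G <- matrix(0, nrow = length(base), ncol = length(fit$coef))
    for (j in seq_along(fit$coef)) {
      th <- fit$coef
      th[j] <- th[j] + eps
      G[, j] <- (cond_at(multi_states_at(fit, newdata, theta = th),
                         target)$estimate - base) / eps
    }
    se <- sqrt(pmax(0, rowSums((G %*% fit$vcov) * G)))
    out$lower <- pmax(0, base - 1.96 * se)
    out$upper <- pmin(1, base + 1.96 * se)
  }
  out
}

#' Plot conditional-occupancy curves
#'
#' @param object An `occu_multi_fit`.
#' @param newdata Covariate grid; must contain the covariates the fit
#'   uses and, for faceting, an `ecosystem` column.
#' @param target Species index (1 or 2).
#' @param x Name of the covariate to place on the x axis.
#' @param ... Passed to [predict_conditional_curves()].
#' @return A ggplot of conditional occupancy (given the other function
#'   present vs absent) with 95% ribbons.
#' @method autoplot occu_multi_fit
#' @export
autoplot.occu_multi_fit <- function(object, newdata, target = 1,
                                    x = "sqrt_numeric_add_date", ...) {
  d <- predict_conditional_curves(object, newdata, target = target, ...)
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[x]], y = .data$estimate,
                                        colour = .data$condition,
                                        fill = .data$condition))
  if (all(c("lower", "upper") %in% names(d))) {
    gg <- gg + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                                 ymax = .data$upper),
                                    alpha = 0.2, colour = NA)
  }
  gg <- gg + ggplot2::geom_line()
  if ("ecosystem" %in% names(d)) {
    gg <- gg + ggplot2::facet_wrap(~ .data$ecosystem)
  }
  gg + ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(y = "conditional occupancy",
                  colour = "other function", fill = "other function")
}
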