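# independent oracles used across tests; none of these call the package's
# likelihood or fitting code

# direct per-site likelihood of a single-species history (probability scale)
oracle_site_lik <- function(y, psi, p) {
  s <- sum(y)
  K <- length(y)
  if (s > 0) psi * p^s * (1 - p)^(K - s) else psi * (1 - p)^K + (1 - psi)
}

# exhaustive-enumeration likelihood of a paired history: marginalize the
# four joint latent states explicitly
oracle_multi_lik <- function(y1, y2, states, p1, p2) {
  det_lik <- function(z, y, p) {
    if (z == 1) prod(ifelse(y == 1, p, 1 - p)) else as.numeric(sum(y) == 0)
  }
  z_pairs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  sum(vapply(1:4, function(i) {
    z <- z_pairs[[i]]
    states[i] * det_lik(z[1], y1, p1) * det_lik(z[2], y2, p2)
  }, numeric(1)))
}

# brute-force grid maximizer of the intercept-only likelihood over
# (psi, p) in (0,1)^2 at the given resolution
oracle_grid_mle <- function(Y, res = 1e-3) {
  s <- rowSums(Y)
  K <- ncol(Y)
  n_det <- sum(s > 0)
  sum_s <- sum(s[s > 0])
  sum_miss <- sum(K - s[s > 0])
  n0 <- sum(s == 0)
  psis <- seq(res, 1 - res, by = res)
  ps <- psis
  best <- c(psi = NA_real_, p = NA_real_)
  best_ll <- -Inf
  for (p in ps) {
    ll <- n_det * log(psis) + sum_s * log(p) + sum_miss * log(1 - p) +
      n0 * log(psis * (1 - p)^K + (1 - psis))
    i <- which.max(ll)
    if (ll[i] > best_ll) {
      best_ll <- ll[i]
      best <- c(psi = psis[i], p = p)
    }
  }
  list(par = best, loglik = best_ll)
}

# all 0/1 histories of length K, as a matrix with 2^K rows
all_histories <- function(K) {
  as.matrix(expand.grid(rep(list(c(0, 1)), K)))
}

# the 4-site detection history used in several fitting examples
example_history_4 <- function() {
  matrix(c(1, 1, 0,
           0, 0, 0,
           1, 0, 0,
           0, 0, 0), nrow = 4, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
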