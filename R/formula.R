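#' Parse a single-species model specification string
#'
#' The notation pairs a detection formula and an occupancy formula, e.g.
#' `"p ~ 1, psi ~ ecosystem"` or
#' `"p ~ sqrt(numeric.add.date), psi ~ latitude"`. Order of the two clauses
#' is free; `Psi` / `psi` are case-insensitive.
#'
#' @param spec Specification string.
#' @return List with `psi_terms` and `p_terms` (term strings for
#'   [design_matrix()]).
#' @export
parse_occu_spec <- function(spec) {
  if (is.list(spec)) {
    stopifnot(all(c("psi_terms", "p_terms") %in% names(spec)))
    return(spec[c("psi_terms", "p_terms")])
  }
  clauses <- strsplit(spec, ",")[[1]]
  out <- list(psi_terms = NULL, p_terms = NULL)
  for (cl in clauses) {
    bits <- strsplit(cl, "~", fixed = TRUE)[[1]]
    if (length(bits) != 2) {
      stop("cannot parse model clause: '", trimws(cl), "'", call. = FALSE)
    }
    lhs <- tolower(trimws(bits[1]))
    rhs <- trimws(bits[2])
    if (lhs %in% c("psi", "ψ")) {
      out$psi_terms <- rhs
    } else if (lhs == "p") {
      out$p_terms <- rhs
    } else {
      stop("unknown model component '", lhs, "' (expected psi or p)",
           call. = FALSE)
    }
  }
  if (is.null(out$psi_terms) || is.null(out$p_terms)) {
    stop("specification must give both 'p ~ ...' and 'psi ~ ...'",
         call. = FALSE)
  }
  out
}

render_occu_spec <- function(terms) {
  paste0("p ~ ", terms$p_terms, ", psi ~ ", terms$psi_terms)
}

#' Parse a two-species model specification string
#'
#' Natural-parameter formulas of the multivariate Bernoulli model, e.g.
#' `"psi[1] ~ ecosystem, psi[2] ~ ecosystem + sqrt(numeric.add.date),
#' psi[12] ~ ecosystem"`. Detection is intercept-only per species and is
#' not part of the string. Species names (e.g. `psi[mcr]`, `psi[pmo]`,
#' `psi[mcr:pmo]`) are accepted in place of the indices 1, 2, 12 when
#' `species` is given.
#'
#' @param spec Specification string.
#' @param species Optional character pair naming species 1 and 2.
#' @return List with `f1_terms`, `f2_terms`, `f12_terms`.
#' @export
parse_multi_spec <- function(spec, species = NULL) {
  if (is.list(spec)) {
    stopifnot(all(c("f1_terms", "f2_terms", "f12_terms") %in% names(spec)))
    return(spec[c("f1_terms", "f2_terms", "f12_terms")])
  }
  keys <- c("1", "2", "12")
  if (!is.null(species)) {
    alias <- c(species, paste0(species[1], ":", species[2]))
  } else {
    alias <- keys
  }
  clauses <- strsplit(spec, ",(?![^\\[]*\\])", perl = TRUE)[[1]]
  out <- stats::setNames(vector("list", 3), keys)
  for (cl in clauses) {
    bits <- strsplit(cl, "~", fixed = TRUE)[[1]]
    if (length(bits) != 2) {
      stop("cannot parse model clause: '", trimws(cl), "'", call. = FALSE)
    }
    lhs <- tolower(trimws(bits[1]))
    m <- regmatches(lhs, regexec("^psi\\[(.+)\\]$", lhs))[[1]]
    if (length(m) != 2) {
      stop("expected psi[1], psi[2] or psi[12] on the left of '~', got '",
           lhs, "'", call. = FALSE)
    }
    key <- m[2]
    hit <- which(tolower(alias) == key | keys == key)
    if (length(hit) != 1) {
      stop("unknown natural parameter 'psi[", key, "]'", call. = FALSE)
    }
    out[[keys[hit]]] <- trimws(bits[2])
  }
  if (any(vapply(out, is.null, logical(1)))) {
    stop("specification must give psi[1], psi[2] and psi[12]",
         call. = FALSE)
  }
  list(f1_terms = out[["1"]], f2_terms = out[["2"]],
       f12_terms = out[["12"]])
}

render_multi_spec <- function(terms) {
  paste0("psi[1] ~ ", terms$f1_terms, ", psi[2] ~ ", terms$f2_terms,
         ", psi[12] ~ ", terms$f12_terms, ", p ~ 1")
}
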