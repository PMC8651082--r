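#' Define a marker panel
#'
#' A marker panel maps one function of interest (the "species" of the
#' occupancy model) to the ordered set of marker genes that act as its
#' replicate surveys. The survey index of a detection history follows the
#' order of `markers`, which is fixed at construction.
#'
#' @param function_name Short name of the function, e.g. `"MCR"` or `"pMMO"`.
#' @param markers Character vector of marker symbols (unique, length >= 1),
#'   e.g. `c("McrA", "McrB", "McrG")`.
#' @param ko_ids Character vector of KEGG Orthology identifiers, one per
#'   marker (recycled from `NA` if not supplied).
#' @return A `marker_panel` object: a tibble with one row per marker and
#'   attributes `function_name`.
#' @examples
#' marker_panel("MCR", c("McrA", "McrB", "McrG"),
#'              c("K00399", "K00401", "K00402"))
#' @export
marker_panel <- function(function_name, markers, ko_ids = NA_character_) {
  stopifnot(is.character(function_name), length(function_name) == 1,
            nzchar(function_name))
  markers <- as.character(markers)
  if (length(markers) < 1) {
    stop("a marker panel needs at least one marker", call. = FALSE)
  }
  if (anyDuplicated(markers)) {
    stop("marker symbols must be unique within a panel: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  }
  ko_ids <- rep_len(as.character(ko_ids), length(markers))
  out <- tibble::tibble(
    marker = markers,
    ko_id = ko_ids,
    survey = seq_along(markers)
  )
  attr(out, "function_name") <- function_name
  class(out) <- c("marker_panel", class(out))
  out
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", attr(x, "function_name"), " (K = ", nrow(x),
      " surveys)\n", sep = "")
  NextMethod()
}

#' Built-in methane-cycle marker panels
#'
#' The two enzyme-complex panels used throughout the package:
#' methyl-coenzyme M reductase (MCR, subunits McrABG; methanogenesis) and
#' particulate methane monooxygenase (pMMO, subunits PmoABC; aerobic
#' methanotrophy), with their KEGG Orthology identifiers. Note that the Pmo
#' KOs are shared with the ammonia monooxygenase (Amo) homologs, which is
#' why downstream curation against labeled references is required.
#'
#' @return A `marker_panel`.
#' @export
mcr_panel <- function() {
  marker_panel("MCR", c("McrA", "McrB", "McrG"),
               c("K00399", "K00401", "K00402"))
}

#' @rdname mcr_panel
#' @export
pmo_panel <- function() {
  marker_panel("pMMO", c("PmoA", "PmoB", "PmoC"),
               c("K10944", "K10945", "K10946"))
}
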