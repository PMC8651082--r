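#' Protein-specific length window from true-positive references
#'
#' The window spans the shortest true-positive reference minus 50 amino
#' acids to the longest plus 50, floored at 1 residue. False-positive
#' references are ignored: the window describes the target protein family,
#' not its confounders.
#'
#' @param refs Reference set: a data frame with at least columns `marker`,
#'   `label` (`"true_positive"` / `"false_positive"`) and either `length`
#'   or `sequence` (lengths are then computed).
#' @param marker Marker symbol to compute the window for.
#' @param slack Residues added on both sides (default 50).
#' @return Named numeric vector `c(min_len, max_len)`.
#' @export
length_window <- function(refs, marker, slack = 50) {
  refs <- as_reference_set(refs)
  tp <- refs[refs$marker == marker & refs$label == "true_positive", ]
  if (nrow(tp) == 0) {
    stop("no true-positive reference sequences for marker '", marker, "'",
         call. = FALSE)
  }
  c(min_len = max(1, min(tp$length) - slack),
    max_len = max(tp$length) + slack)
}

# normalize a reference table: require marker/label, derive length
as_reference_set <- function(refs) {
  refs <- tibble::as_tibble(refs)
  need <- c("marker", "label")
  if (!all(need %in% names(refs))) {
    stop("reference set needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(refs$label), c("true_positive", "false_positive"))
  if (length(bad)) {
    stop("reference labels must be 'true_positive' or 'false_positive', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"length" %in% names(refs)) {
    if (!"sequence" %in% names(refs)) {
      stop("reference set needs a 'length' or 'sequence' column", call. = FALSE)
    }
    refs$length <- nchar(refs$sequence)
  }
  stopifnot(all(refs$length > 0))
  refs
}

#' Partition candidate sequences by a length window
#'
#' @param cands Candidate table with columns `seq_id` and `length` (or
#'   `sequence`).
#' @param window Output of [length_window()].
#' @return The candidate table with logical `kept` and character `reason`
#'   (`"clean"`, `"too_short"`, `"too_long"`) columns appended. Both window
#'   boundaries are inclusive.
#' @export
filter_by_length <- function(cands, window) {
  cands <- tibble::as_tibble(cands)
  if (!"length" %in% names(cands)) cands$length <- nchar(cands$sequence)
  dplyr::mutate(
    cands,
    reason = dplyr::case_when(
      .data$length < window[["min_len"]] ~ "too_short",
      .data$length > window[["max_len"]] ~ "too_long",
      TRUE ~ "clean"
    ),
    kept = .data$reason == "clean"
  )
}

#' Read tabular homology-search hits (blast/diamond outfmt 6)
#'
#' Parses the 12-column tab-separated dialect
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore).
#'
#' @param path Path to the tab-separated hit table (no header).
#' @return Tibble with those 12 columns.
#' @export
read_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hits <- tryCatch(
    readr::read_tsv(path, col_names = cols,
                    col_types = "ccdiiiiiiidd", progress = FALSE),
    error = function(e) stop("malformed hit table '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  prob <- readr::problems(hits)
  if (nrow(prob) > 0) {
    stop("malformed hit table '", path, "' at line ", prob$row[1], ": ",
         prob$expected[1], " expected, got ", prob$actual[1], call. = FALSE)
  }
  if (any(!is.finite(hits$bitscore))) {
    stop("non-finite bit score in hit table '", path, "'", call. = FALSE)
  }
  hits
}

#' Classify query sequences by their top database hit
#'
#' A query is kept only if its best hit (maximum bit score) is a reference
#' labeled `true_positive`. Unlabeled subjects are the background database;
#' a top hit there, or to a `false_positive` reference, removes the query.
#' Queries with equal-best bit scores are kept only if *all* tied subjects
#' are labeled true positives (conservative under the no-false-positives
#' assumption). Queries absent from the hit table are removed with reason
#' `"no_hit"`: absence of homology evidence cannot certify a true positive.
#'
#' @param hits Hit table with at least `qseqid`, `sseqid`, `bitscore`
#'   (see [read_hits()]).
#' @param labels Data frame with columns `subject_id`, `label`, or a named
#'   character vector of labels.
#' @param queries Character vector of all query ids under consideration
#'   (defaults to the queries present in `hits`).
#' @return Tibble (`seq_id`, `kept`, `reason`) with reasons `"clean"`,
#'   `"top_hit_false_positive"`, `"no_hit"`. The result is invariant to the
#'   row order of `hits`.
#' @export
classify_by_top_hit <- function(hits, labels, queries = unique(hits$qseqid)) {
  if (is.data.frame(labels)) {
    lab <- stats::setNames(as.character(labels$label),
                           as.character(labels$subject_id))
  } else {
    lab <- labels
  }
  hits <- tibble::as_tibble(hits)
  top <- hits |>
    dplyr::group_by(.data$qseqid) |>
    dplyr::filter(.data$bitscore == max(.data$bitscore)) |>
    dplyr::summarise(
      all_tp = all(!is.na(lab[.data$sseqid]) &
                     lab[.data$sseqid] == "true_positive"),
      .groups = "drop"
    )
  tibble::tibble(seq_id = queries) |>
    dplyr::left_join(top, by = c(seq_id = "qseqid")) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        is.na(.data$all_tp) ~ "no_hit",
        .data$all_tp ~ "clean",
        TRUE ~ "top_hit_false_positive"
      ),
      kept = .data$reason == "clean"
    ) |>
    dplyr::select("seq_id", "kept", "reason")
}

#' Screen query sequences on a phylogenetic tree
#'
#' Operationalizes the removal of sequences that do not cluster with the
#' reference set or sit on extremely long branches. A query leaf is flagged
#' when (a) its nearest labeled reference leaf by patristic distance is a
#' false positive (ties: flagged if *any* tied-nearest is a false positive),
#' or (b) its terminal branch length exceeds
#' `median + c * MAD` of all terminal branch lengths in the tree, with the
#' raw (unscaled) median absolute deviation.
#'
#' @param tree An `ape::phylo` object or a path to a newick file.
#' @param queries Character vector of query leaf labels.
#' @param labels Reference labels as in [classify_by_top_hit()].
#' @param c Long-branch multiplier (default 6). Raising `c` can only grow
#'   the kept set.
#' @return Tibble (`seq_id`, `kept`, `reason`) with reasons `"clean"`,
#'   `"tree_fp_neighbor"`, `"tree_long_branch"`.
#' @export
tree_screen <- function(tree, queries, labels, c = 6) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  # newick single-quoting (needed for '|' in sequence ids) is not stripped
  # by ape's reader
  tree$tip.label <- gsub("^'(.*)'$", "\\1", tree$tip.label)
  if (is.data.frame(labels)) {
    lab <- stats::setNames(as.character(labels$label),
                           as.character(labels$subject_id))
  } else {
    lab <- labels
  }
  missing_q <- setdiff(queries, tree$tip.label)
  if (length(missing_q)) {
    stop("query leaves absent from tree: ",
         paste(missing_q, collapse = ", "), call. = FALSE)
  }
  ref_leaves <- intersect(tree$tip.label, names(lab))
  if (!any(lab[ref_leaves] == "true_positive")) {
    stop("tree contains no true-positive reference leaf", call. = FALSE)
  }

  # terminal branch length per tip (tips are nodes 1..Ntip in the edge
  # matrix)
  tip_idx <- match(seq_along(tree$tip.label), tree$edge[, 2])
  term_len <- tree$edge.length[tip_idx]
  names(term_len) <- tree$tip.label
  cutoff <- stats::median(term_len) +
    c * stats::median(abs(term_len - stats::median(term_len)))

  dmat <- ape::cophenetic.phylo(tree)
  flag_fp <- vapply(queries, function(q) {
    other <- setdiff(ref_leaves, q)
    d <- dmat[q, other]
    near <- other[d == min(d)]
    any(lab[near] == "false_positive")
  }, logical(1))

  tibble::tibble(
    seq_id = queries,
    reason = dplyr::case_when(
      flag_fp ~ "tree_fp_neighbor",
      term_len[queries] > cutoff ~ "tree_long_branch",
      TRUE ~ "clean"
    ),
    kept = .data$reason == "clean"
  )
}

#' Run the full marker-curation pipeline
#'
#' Composes the three screens — protein-specific length window, labeled
#' top-hit classification, and (optionally) tree screening — and tallies
#' per-metagenome presence evidence for each marker of the panel. Every
#' candidate appears exactly once in the disposition ledger, and stage
#' counts are monotone non-increasing.
#'
#' @param panel A [marker_panel()].
#' @param refs Labeled reference set (see [length_window()]).
#' @param cands Candidate table with columns `seq_id`, `metagenome_id`,
#'   `marker` and `sequence` or `length`.
#' @param hits Homology hit table (see [read_hits()]).
#' @param tree Optional newick path or `phylo`; when `NULL` the tree stage
#'   is skipped and recorded as such in the report.
#' @param labels Reference labels; defaults to those in `refs`
#'   (`id` + `label` columns).
#' @param tree_c Long-branch multiplier passed to [tree_screen()].
#' @return A list with `evidence` (tibble `metagenome_id`, `marker`,
#'   `n_sequences`, curated counts only) and `report` (a `curation_report`:
#'   stage counts plus the per-sequence disposition ledger).
#' @export
curate <- function(panel, refs, cands, hits, tree = NULL,
                   labels = NULL, tree_c = 6) {
  refs <- as_reference_set(refs)
  cands <- tibble::as_tibble(cands)
  if (!"length" %in% names(cands)) cands$length <- nchar(cands$sequence)
  unknown <- setdiff(unique(cands$marker), panel$marker)
  if (length(unknown)) {
    stop("candidate markers not in panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- tibble::tibble(subject_id = refs$id, label = refs$label)
  }
  if (nrow(cands) == 0) {
    report <- structure(
      list(stage_counts = tibble::tibble(
             stage = c("initial", "after_length", "after_top_hit",
                       "after_tree"),
             n = rep(0L, 4)),
           dispositions = tibble::tibble(seq_id = character(),
                                         metagenome_id = character(),
                                         marker = character(),
                                         kept = logical(),
                                         reason = character()),
           tree_stage_skipped = is.null(tree), tree_c = tree_c),
      class = "curation_report")
    return(list(evidence = tibble::tibble(metagenome_id = character(),
                                          marker = character(),
                                          n_sequences = integer()),
                report = report))
  }

  # stage 1: per-marker length windows
  lengths_ok <- cands |>
    dplyr::group_by(.data$marker) |>
    dplyr::group_modify(function(d, key) {
      w <- length_window(refs, key$marker)
      filter_by_length(d, w)
    }) |>
    dplyr::ungroup()
  disp <- dplyr::select(lengths_ok, "seq_id", "metagenome_id", "marker",
                        "reason", "kept") |>
    dplyr::mutate(stage = ifelse(.data$kept, NA_character_, "length"))

  # stage 2: top-hit classification of length survivors
  s1 <- disp$seq_id[disp$kept]
  th <- classify_by_top_hit(hits, labels, queries = s1)
  disp <- disp |>
    dplyr::left_join(th, by = "seq_id", suffix = c("", ".th")) |>
    dplyr::mutate(
      stage = dplyr::if_else(.data$kept & !is.na(.data$kept.th) &
                               !.data$kept.th, "top_hit", .data$stage),
      reason = dplyr::if_else(.data$kept, dplyr::coalesce(.data$reason.th,
                                                          .data$reason),
                              .data$reason),
      kept = .data$kept & dplyr::coalesce(.data$kept.th, TRUE)
    ) |>
    dplyr::select(-"kept.th", -"reason.th")

  # stage 3: tree screen (optional)
  tree_skipped <- is.null(tree)
  if (!tree_skipped) {
    s2 <- disp$seq_id[disp$kept]
    if (length(s2)) {
      ts <- tree_screen(tree, s2, labels, c = tree_c)
      disp <- disp |>
        dplyr::left_join(ts, by = "seq_id", suffix = c("", ".ts")) |>
        dplyr::mutate(
          stage = dplyr::if_else(.data$kept & !is.na(.data$kept.ts) &
                                   !.data$kept.ts, "tree", .data$stage),
          reason = dplyr::if_else(.data$kept, dplyr::coalesce(.data$reason.ts,
                                                              .data$reason),
                                  .data$reason),
          kept = .data$kept & dplyr::coalesce(.data$kept.ts, TRUE)
        ) |>
        dplyr::select(-"kept.ts", -"reason.ts")
    }
  }

  stage_counts <- tibble::tibble(
    stage = c("initial", "after_length", "after_top_hit", "after_tree"),
    n = c(nrow(disp),
          sum(is.na(disp$stage) | disp$stage != "length"),
          sum(disp$kept) + sum(disp$stage %in% "tree"),
          sum(disp$kept))
  )

  evidence <- disp |>
    dplyr::filter(.data$kept) |>
    dplyr::count(.data$metagenome_id, .data$marker, name = "n_sequences")

  report <- structure(
    list(stage_counts = stage_counts,
         dispositions = dplyr::select(disp, "seq_id", "metagenome_id",
                                      "marker", "kept", "reason"),
         tree_stage_skipped = tree_skipped,
         tree_c = tree_c),
    class = "curation_report"
  )
  list(evidence = evidence, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report>\n")
  for (i in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  %-14s %d\n", x$stage_counts$stage[i], x$stage_counts$n[i]))
  }
  if (x$tree_stage_skipped) cat("  (tree stage skipped: no tree supplied)\n")
  invisible(x)
}

#' Read candidate protein sequences from FASTA
#'
#' Sequence ids are expected to carry the metagenome id and marker symbol as
#' `metagenomeID|marker|localID` (delimiter configurable).
#'
#' @param path FASTA file of amino-acid sequences.
#' @param delim Field delimiter inside the sequence id.
#' @return Tibble (`seq_id`, `metagenome_id`, `marker`, `sequence`, `length`).
#' @export
read_candidates <- function(path, delim = "|") {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  parts <- stringr::str_split_fixed(ids, stringr::fixed(delim), 3)
  if (any(parts[, 1] == "" | parts[, 2] == "")) {
    stop("sequence ids must look like metagenomeID", delim, "marker", delim,
         "localID", call. = FALSE)
  }
  tibble::tibble(
    seq_id = ids,
    metagenome_id = parts[, 1],
    marker = parts[, 2],
    sequence = as.character(seqs),
    length = Biostrings::width(seqs)
  )
}

#' Read a reference label file
#'
#' @param path Delimited file with columns `subject_id`, `label`.
#' @param delim Field delimiter (default comma).
#' @return Tibble (`subject_id`, `label`).
#' @export
read_labels <- function(path, delim = ",") {
  readr::read_delim(path, delim = delim, col_types = "cc", progress = FALSE)
}
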