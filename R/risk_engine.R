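#' Risk-decision thresholds
#'
#' The conjunctive alignment-tier criteria: a query with no exact peptide
#' match is flagged as a possible risk when some panel alignment reaches at
#' least `min_identity_pct` percent identity AND an expectation value
#' strictly below `max_e_score` AND an overlap of at least `min_overlap`
#' alignment columns. Defaults are the published screening guideline values
#' (45 percent, 1e-14, 100 AA). Boundary semantics: identity >= 45.0
#' passes, E < 1e-14 passes, overlap >= 100 passes.
#'
#' @param min_identity_pct Minimum percent identity, in (0, 100].
#' @param max_e_score Maximum (exclusive) expectation value, > 0.
#' @param min_overlap Minimum alignment overlap in columns, >= 1.
#' @return A list of class `ced_thresholds`.
#' @export
ced_thresholds <- function(min_identity_pct = 45, max_e_score = 1e-14,
                           min_overlap = 100L) {
  if (!(min_identity_pct > 0 && min_identity_pct <= 100))
    stop("min_identity_pct must be in (0, 100]", call. = FALSE)
  if (!(max_e_score > 0)) stop("max_e_score must be > 0", call. = FALSE)
  if (!(min_overlap >= 1)) stop("min_overlap must be >= 1", call. = FALSE)
  structure(list(min_identity_pct = min_identity_pct,
                 max_e_score = max_e_score,
                 min_overlap = as.integer(min_overlap)),
            class = "ced_thresholds")
}

#' Does an alignment meet the possible-risk criteria?
#'
#' Vectorized over the three statistics; all three criteria must hold.
#'
#' @param identity_pct Percent identity (gaps counted in the denominator).
#' @param e_score Expectation value.
#' @param overlap_len Alignment overlap in columns.
#' @param thresholds A [ced_thresholds()].
#' @return Logical vector.
#' @examples
#' th <- ced_thresholds()
#' alignment_meets_criteria(98.9, 1.1e-73, 264, th)  # TRUE
#' alignment_meets_criteria(40.5, 9.1e-09, 168, th)  # FALSE
#' @export
alignment_meets_criteria <- function(identity_pct, e_score, overlap_len,
                                     thresholds = ced_thresholds()) {
  stopifnot(inherits(thresholds, "ced_thresholds"))
  identity_pct >= thresholds$min_identity_pct &
    e_score < thresholds$max_e_score &
    overlap_len >= thresholds$min_overlap
}

#' Classify one query protein for CeD risk
#'
#' The two-tier decision procedure. Tier one: any exact occurrence of a
#' database peptide in the query yields `probable_risk` immediately (the
#' alignment tier is then not consulted for the verdict). Tier two: with no
#' exact hit, the query is locally aligned to every representative CeD
#' protein; if any alignment meets all three threshold criteria the verdict
#' is `possible_risk`, otherwise `no_significant_similarity`. Verdicts are
#' screening flags: flagged proteins should be tested further with
#' CeD-specific CD4/CD8+ T-cell assays, not declared harmful or safe.
#'
#' @param query Protein record or sequence string.
#' @param index A `ced_match_index` ([build_peptide_index()]).
#' @param panel Representative CeD protein panel (data frame of records).
#' @param thresholds A [ced_thresholds()].
#' @param config An [align_config()].
#' @return An object of class `ced_verdict`: list with `query_id`,
#'   `category` (one of `probable_risk`, `possible_risk`,
#'   `no_significant_similarity`), `exact_hits` (data frame),
#'   `best_alignment` (one-row data frame or `NULL` when the panel tier was
#'   not consulted), `alignments` (full panel results or `NULL`), and a
#'   human-readable `rationale` naming the triggering hit or the best failed
#'   criterion, including the gap fraction of the best alignment.
#' @export
classify_protein <- function(query, index, panel,
                             thresholds = ced_thresholds(),
                             config = align_config()) {
  stopifnot(inherits(thresholds, "ced_thresholds"))
  q <- .as_single_record(query)
  hits <- find_exact_matches(q, index)
  if (nrow(hits) > 0L) {
    n_pep <- length(unique(hits$peptide_seq))
    return(structure(list(
      query_id = q$id, category = "probable_risk", exact_hits = hits,
      best_alignment = NULL, alignments = NULL,
      rationale = sprintf(
        "exact match: %d occurrence(s) of %d distinct CeD peptide(s), first '%s' at [%d, %d]",
        nrow(hits), n_pep, hits$peptide_seq[1L], hits$start[1L], hits$end[1L])),
      class = "ced_verdict"))
  }
  alns <- align_panel(q, panel, config)
  pass <- alignment_meets_criteria(alns$identity_pct, alns$e_score,
                                   alns$overlap_len, thresholds)
  best <- if (any(pass)) alns[which(pass)[1L], , drop = FALSE]
          else alns[1L, , drop = FALSE]
  gap_frac <- if (best$overlap_len > 0) best$gap_columns / best$overlap_len else NA_real_
  if (any(pass)) {
    category <- "possible_risk"
    rationale <- sprintf(
      "alignment to '%s' meets all criteria: identity %.1f%% >= %.1f%%, E %.3g < %.3g, overlap %d >= %d (gap fraction %.3f)",
      best$subject_id, best$identity_pct, thresholds$min_identity_pct,
      best$e_score, thresholds$max_e_score, best$overlap_len,
      thresholds$min_overlap, gap_frac)
  } else {
    category <- "no_significant_similarity"
    fails <- c(
      if (best$identity_pct < thresholds$min_identity_pct)
        sprintf("identity %.1f%% < %.1f%%", best$identity_pct,
                thresholds$min_identity_pct),
      if (best$e_score >= thresholds$max_e_score)
        sprintf("E %.3g >= %.3g", best$e_score, thresholds$max_e_score),
      if (best$overlap_len < thresholds$min_overlap)
        sprintf("overlap %d < %d", best$overlap_len, thresholds$min_overlap))
    rationale <- sprintf(
      "no exact peptide match; best alignment ('%s') fails: %s (gap fraction %.3f)",
      best$subject_id, paste(fails, collapse = "; "), gap_frac)
  }
  structure(list(query_id = q$id, category = category,
                 exact_hits = hits, best_alignment = best,
                 alignments = alns, rationale = rationale),
            class = "ced_verdict")
}

#' @export
print.ced_verdict <- function(x, ...) {
  cat(sprintf("%s: %s\n  %s\n", x$query_id, x$category, x$rationale))
  invisible(x)
}

#' Classify a batch of query proteins
#'
#' Order-preserving batch classification with a per-category summary and,
#' when group labels are supplied, a per-group report in the shape of the
#' published validation tables: whether any group member contains an exact
#' CeD peptide, and the group's three best alignments by percent identity
#' (reported as overlap length, subject length, identity, E-score).
#'
#' @param queries Data frame of protein records (optionally with a `group`
#'   column) or named character vector of sequences.
#' @param index A `ced_match_index`.
#' @param panel Representative protein panel.
#' @param thresholds A [ced_thresholds()].
#' @param config An [align_config()].
#' @param groups Optional character vector of group labels, one per query;
#'   overrides a `group` column.
#' @return List of class `ced_batch` with `verdicts` (data frame: query_id,
#'   group, category, n_exact_occurrences, n_distinct_peptides,
#'   best_identity_pct, best_overlap_len, best_subject_len, best_e_score,
#'   rationale), `summary` (named counts over the three categories),
#'   `group_report` (data frame or `NULL`), and `details` (list of
#'   `ced_verdict`).
#' @export
classify_batch <- function(queries, index, panel,
                           thresholds = ced_thresholds(),
                           config = align_config(), groups = NULL) {
  if (is.null(groups) && is.data.frame(queries) && "group" %in% names(queries))
    groups <- queries$group
  queries <- as_protein_records(if (is.character(queries)) queries else
    queries[, intersect(names(queries), c("id", "description", "sequence")),
            drop = FALSE])
  if (is.null(groups)) groups <- rep(NA_character_, nrow(queries))
  if (length(groups) != nrow(queries))
    stop("groups must have one label per query", call. = FALSE)

  details <- lapply(seq_len(nrow(queries)), function(i)
    classify_protein(queries[i, , drop = FALSE], index, panel, thresholds,
                     config))
  verdicts <- do.call(rbind, lapply(seq_along(details), function(i) {
    v <- details[[i]]
    ba <- v$best_alignment
    data.frame(
      query_id = v$query_id,
      group = groups[i],
      category = v$category,
      n_exact_occurrences = nrow(v$exact_hits),
      n_distinct_peptides = length(unique(v$exact_hits$peptide_seq)),
      best_identity_pct = if (is.null(ba)) NA_real_ else ba$identity_pct,
      best_overlap_len = if (is.null(ba)) NA_integer_ else ba$overlap_len,
      best_subject_len = if (is.null(ba)) NA_integer_ else ba$subject_len,
      best_e_score = if (is.null(ba)) NA_real_ else ba$e_score,
      rationale = v$rationale,
      stringsAsFactors = FALSE)
  }))
  if (is.null(verdicts))
    verdicts <- data.frame(query_id = character(), group = character(),
                           category = character(),
                           n_exact_occurrences = integer(),
                           n_distinct_peptides = integer(),
                           best_identity_pct = numeric(),
                           best_overlap_len = integer(),
                           best_subject_len = integer(),
                           best_e_score = numeric(),
                           rationale = character(), stringsAsFactors = FALSE)

  cats <- c("probable_risk", "possible_risk", "no_significant_similarity")
  summary <- vapply(cats, function(k) sum(verdicts$category == k), integer(1L))

  group_report <- NULL
  if (nrow(verdicts) > 0L && any(!is.na(verdicts$group))) {
    group_report <- do.call(rbind, lapply(
      split(seq_len(nrow(verdicts)), verdicts$group), function(ix) {
        # pool every panel alignment of the group, rank by identity
        alns <- do.call(rbind, lapply(details[ix], function(v) v$alignments))
        top <- if (is.null(alns)) NULL else {
          alns <- alns[order(-alns$identity_pct, alns$e_score), , drop = FALSE]
          utils::head(alns, 3L)
        }
        k <- if (is.null(top)) 0L else nrow(top)
        data.frame(
          group = verdicts$group[ix[1L]],
          n_queries = length(ix),
          contains_exact_peptides = any(verdicts$n_exact_occurrences[ix] > 0L),
          rank = if (k) seq_len(k) else NA_integer_,
          overlap_len = if (k) top$overlap_len else NA_integer_,
          subject_len = if (k) top$subject_len else NA_integer_,
          identity_pct = if (k) top$identity_pct else NA_real_,
          e_score = if (k) top$e_score else NA_real_,
          stringsAsFactors = FALSE)
      }))
    rownames(group_report) <- NULL
  }

  structure(list(verdicts = verdicts, summary = summary,
                 group_report = group_report, details = details),
            class = "ced_batch")
}

#' @export
print.ced_batch <- function(x, ...) {
  cat("CeD risk screening of", nrow(x$verdicts), "quer(ies):\n")
  for (k in names(x$summary))
    cat(sprintf("  %-26s %d\n", k, x$summary[[k]]))
  if (!is.null(x$group_report)) {
    cat("Per-group best alignments (overlap (subject_len), % identity, E-score):\n")
    gr <- x$group_report
    for (i in seq_len(nrow(gr)))
      cat(sprintf("  %-12s %3d (%3d)  %5.1f  %.2g\n", gr$group[i],
                  gr$overlap_len[i], gr$subject_len[i], gr$identity_pct[i],
                  gr$e_score[i]))
  }
  invisible(x)
}
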