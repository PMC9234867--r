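#' Build a multi-pattern peptide match index
#'
#' Compiles a peptide database into an index supporting one-pass scanning of
#' query proteins for exact occurrences of any database peptide. Index
#' construction is independent of any query. Native and deamidated forms are
#' both indexed verbatim; the query is never auto-deamidated here (the
#' database already carries predicted deamidated peptides).
#'
#' @param db A `ced_peptide_db` (see [peptide_db()]), or a data frame in its
#'   row format.
#' @return An opaque object of class `ced_match_index`.
#' @export
build_peptide_index <- function(db) {
  if (is.data.frame(db)) db <- peptide_db(db)
  stopifnot(inherits(db, "ced_peptide_db"))
  pep <- db$peptides
  if (nrow(pep) == 0L)
    stop("cannot build a match index from an empty peptide database",
         call. = FALSE)
  structure(list(
    peptides = pep,
    patterns = Biostrings::AAStringSet(pep$sequence),
    version_label = db$version_label
  ), class = "ced_match_index")
}

#' @export
print.ced_match_index <- function(x, ...) {
  cat(sprintf("CeD exact-match index over %d peptides ('%s')\n",
              nrow(x$peptides), x$version_label))
  invisible(x)
}

#' Find all exact peptide matches in a query protein
#'
#' Reports every occurrence of every indexed peptide within the query,
#' including overlapping and nested hits, sorted by `(start, end)`.
#' Matching is exact after canonicalization; an `X` in the query never
#' matches any peptide residue.
#'
#' @param query A single protein record (one-row data frame with `id` and
#'   `sequence`, or a named length-1 character vector), or a bare sequence
#'   string (id `"query"`).
#' @param index A `ced_match_index` from [build_peptide_index()].
#' @return Data frame of hits with columns `query_id`, `peptide_seq`,
#'   `start`, `end` (1-based closed interval), `form`, `evidence`.
#' @examples
#' idx <- build_peptide_index(peptide_db(reference_peptides()))
#' find_exact_matches(c(q1 = "AAQLIPCMDVVLAA"), idx)
#' @export
find_exact_matches <- function(query, index) {
  stopifnot(inherits(index, "ced_match_index"))
  q <- .as_single_record(query)
  subject <- Biostrings::AAString(q$sequence)
  pep <- index$peptides
  hits <- vector("list", nrow(pep))
  for (i in seq_len(nrow(pep))) {
    m <- Biostrings::matchPattern(index$patterns[[i]], subject, fixed = TRUE)
    if (length(m) == 0L) next
    hits[[i]] <- data.frame(
      query_id = q$id,
      peptide_seq = pep$sequence[i],
      start = BiocGenerics::start(m),
      end = BiocGenerics::end(m),
      form = pep$form[i],
      evidence = pep$evidence[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(query_id = character(), peptide_seq = character(),
                      start = integer(), end = integer(), form = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end, out$peptide_seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Does a query contain any database peptide?
#'
#' Short-circuits on the first occurrence found.
#'
#' @inheritParams find_exact_matches
#' @return Logical scalar.
#' @export
contains_ced_peptide <- function(query, index) {
  stopifnot(inherits(index, "ced_match_index"))
  q <- .as_single_record(query)
  subject <- Biostrings::AAString(q$sequence)
  for (i in seq_along(index$patterns)) {
    if (length(Biostrings::matchPattern(index$patterns[[i]], subject,
                                        fixed = TRUE)) > 0L)
      return(TRUE)
  }
  FALSE
}

# Normalize the many shapes a "one protein" argument can take.
.as_single_record <- function(query) {
  if (is.character(query) && length(query) == 1L && is.null(names(query)))
    query <- c(query = unname(query))
  rec <- as_protein_records(query)
  if (nrow(rec) != 1L)
    stop("expected a single protein record, got ", nrow(rec), call. = FALSE)
  rec
}
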