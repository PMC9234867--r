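#' @importFrom Biostrings readBStringSet writeXStringSet AAStringSet AAString matchPattern
#' @importFrom BiocGenerics start end width score
NULL

# 20 standard residues; X carries ambiguity in proteins but is banned in peptides
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Canonicalize and validate an amino-acid sequence
#'
#' Uppercases, strips all whitespace and trailing `*` stop characters, then
#' checks every residue against the 20-letter amino-acid alphabet
#' (`ACDEFGHIKLMNPQRSTVWY`), optionally extended with `X` for unknown
#' residues.
#'
#' @param raw Character scalar, the raw sequence.
#' @param allow_x Logical; accept `X` as an unknown residue (the default for
#'   query proteins). Peptide records must set this to `FALSE`: an epitope
#'   claim requires exact residues.
#' @param what Label used in error messages (e.g. a record id).
#' @return The canonical uppercase sequence string.
#' @examples
#' validate_sequence("lqlqpf ")                 # "LQLQPF"
#' nchar(validate_sequence("LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF"))  # 33
#' @export
validate_sequence <- function(raw, allow_x = TRUE, what = "sequence") {
  if (length(raw) != 1L || is.na(raw) || !is.character(raw))
    stop(what, ": sequence must be a single character string", call. = FALSE)
  s <- toupper(gsub("[[:space:]]+", "", raw))
  s <- sub("\\*+$", "", s)
  if (nchar(s) == 0L)
    stop(what, ": empty sequence after stripping whitespace", call. = FALSE)
  alphabet <- if (allow_x) c(AA_ALPHABET20, "X") else AA_ALPHABET20
  chars <- strsplit(s, "")[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0L)
    stop(sprintf("%s: illegal residue '%s' at position %d", what,
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  s
}

#' Read protein records from FASTA
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file or text into a
#' data frame of protein records. Sequences are uppercased, line wraps and
#' trailing whitespace removed, and `*` terminators stripped. The record id
#' is the first whitespace-delimited token of the header; the rest is kept
#' as the description.
#'
#' @param file Path to a FASTA file, a connection, or a character vector of
#'   FASTA-formatted lines (anything containing a newline or starting with
#'   `>` is treated as literal text).
#' @param allow_x Logical, passed to [validate_sequence()].
#' @return A data frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(file, allow_x = TRUE) {
  path <- .as_local_file(file)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA format error: no records found", call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == ""))
    stop("FASTA format error: record with empty id", call. = FALSE)
  if (anyDuplicated(ids))
    stop("FASTA format error: duplicate record id '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  seqs <- vapply(seq_along(set), function(i) {
    validate_sequence(as.character(set[[i]]), allow_x = allow_x, what = ids[i])
  }, character(1L))
  data.frame(id = ids, description = desc, sequence = seqs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_fasta <- function(records, file) {
  records <- as_protein_records(records)
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, filepath = file, width = 60L)
  invisible(file)
}

#' Coerce to a validated protein record data frame
#'
#' Accepts a data frame (columns `id`, `sequence`, optional `description`)
#' or a named character vector of sequences, and returns the canonical
#' record data frame with validated sequences and unique ids.
#'
#' @param x Data frame or named character vector.
#' @return Data frame with columns `id`, `description`, `sequence`.
#' @export
as_protein_records <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids) || any(!nzchar(ids)))
      stop("protein sequences given as a character vector must be named",
           call. = FALSE)
    x <- data.frame(id = ids, description = "", sequence = unname(x),
                    stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x), all(c("id", "sequence") %in% names(x)))
  if (!"description" %in% names(x)) x$description <- rep("", nrow(x))
  if (anyDuplicated(x$id))
    stop("duplicate protein id '", x$id[duplicated(x$id)][1L], "'",
         call. = FALSE)
  x$sequence <- vapply(seq_len(nrow(x)), function(i)
    validate_sequence(x$sequence[i], allow_x = TRUE, what = x$id[i]),
    character(1L))
  x[, c("id", "description", "sequence")]
}

#' Read a CeD peptide table
#'
#' Reads a comma- or tab-delimited table (dialect auto-detected from the
#' header line) with at least the columns `sequence`, `form`, `evidence` and
#' optionally `t_cell` and `references`, validates every row, merges
#' duplicate sequences, and returns a peptide database object.
#'
#' Rows are rejected (with a recorded reason, never silently) when the
#' peptide is shorter than nine residues — too short to occupy the MHC class
#' II groove and activate T cells — when the `form` or `evidence` value is
#' unknown, when the sequence contains a non-standard residue, or when a
#' record marked `deamidated` contains no glutamic acid.
#'
#' @param file Path, connection, or character text of the table.
#' @param dialect `"auto"` (default), `"csv"` or `"tsv"`.
#' @param version_label Free-text label stored on the database.
#' @return A `ced_peptide_db` object; see [peptide_db()].
#' @export
read_peptide_table <- function(file, dialect = c("auto", "csv", "tsv"),
                               version_label = "user") {
  dialect <- match.arg(dialect)
  path <- .as_local_file(file)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L)
    stop("peptide table format error: empty input", call. = FALSE)
  sep <- switch(dialect,
                csv = ",",
                tsv = "\t",
                auto = if (grepl("\t", header)) "\t" else ",")
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", strip.white = TRUE)
  need <- c("sequence", "form", "evidence")
  if (!all(need %in% names(tab)))
    stop("peptide table format error: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  peptide_db(tab, version_label = version_label)
}

#' Build a validated peptide database
#'
#' Constructor for the `ced_peptide_db` class: a set of CeD-associated
#' peptide records keyed by sequence. Each record carries its `form`
#' (`native` or `deamidated`), `evidence` class (`immunogenic` or `toxic`),
#' optional `t_cell` reactivity (`CD4`, `CD8`, `none`) and reference
#' strings. Invalid rows are rejected with a reason and counted, duplicate
#' sequences are merged (references unioned, first-seen metadata kept).
#'
#' @param peptides Data frame with columns `sequence`, `form`, `evidence`
#'   and optionally `t_cell`, `references`.
#' @param version_label Free-text database label.
#' @return An object of class `ced_peptide_db` with elements `peptides`
#'   (validated data frame), `version_label`, `n_rejected` and `rejected`
#'   (data frame of row, sequence, reason).
#' @export
peptide_db <- function(peptides, version_label = "user") {
  stopifnot(is.data.frame(peptides))
  if (!"t_cell" %in% names(peptides)) peptides$t_cell <- "none"
  if (!"references" %in% names(peptides)) peptides$references <- ""
  peptides$t_cell[is.na(peptides$t_cell) | !nzchar(peptides$t_cell)] <- "none"
  peptides$references[is.na(peptides$references)] <- ""

  keep <- logical(nrow(peptides))
  reason <- character(nrow(peptides))
  seqs <- character(nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    s <- tryCatch(validate_sequence(peptides$sequence[i], allow_x = FALSE,
                                    what = paste0("row ", i)),
                  error = function(e) conditionMessage(e))
    if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", s)) {
      reason[i] <- s  # validation error message
      next
    }
    if (nchar(s) < 9L) {
      reason[i] <- "below 9 AA minimum"
      next
    }
    form <- tolower(peptides$form[i])
    if (!form %in% c("native", "deamidated")) {
      reason[i] <- paste0("unknown form value '", peptides$form[i], "'")
      next
    }
    evd <- tolower(peptides$evidence[i])
    if (!evd %in% c("immunogenic", "toxic")) {
      reason[i] <- paste0("unknown evidence value '", peptides$evidence[i], "'")
      next
    }
    tc <- peptides$t_cell[i]
    if (!tc %in% c("CD4", "CD8", "none")) {
      reason[i] <- paste0("unknown t_cell value '", tc, "'")
      next
    }
    if (form == "deamidated" && !grepl("E", s)) {
      reason[i] <- "deamidated record without glutamic acid"
      next
    }
    keep[i] <- TRUE
    seqs[i] <- s
    peptides$form[i] <- form
    peptides$evidence[i] <- evd
  }

  rejected <- data.frame(row = which(!keep),
                         sequence = peptides$sequence[!keep],
                         reason = reason[!keep], stringsAsFactors = FALSE)
  ok <- peptides[keep, , drop = FALSE]
  ok$sequence <- seqs[keep]

  # sequence is the identity key: merge metadata on collision
  if (nrow(ok) > 0L) {
    merged <- do.call(rbind, lapply(split(ok, ok$sequence), function(g) {
      refs <- unique(unlist(strsplit(g$references, ";", fixed = TRUE)))
      refs <- refs[nzchar(refs)]
      out <- g[1L, , drop = FALSE]
      out$references <- paste(refs, collapse = ";")
      out
    }))
    merged <- merged[order(match(merged$sequence, ok$sequence)), , drop = FALSE]
    rownames(merged) <- NULL
    ok <- merged[, c("sequence", "form", "evidence", "t_cell", "references")]
  } else {
    ok <- data.frame(sequence = character(), form = character(),
                     evidence = character(), t_cell = character(),
                     references = character(), stringsAsFactors = FALSE)
  }

  structure(list(peptides = ok, version_label = version_label,
                 n_rejected = nrow(rejected), rejected = rejected),
            class = "ced_peptide_db")
}

#' @export
print.ced_peptide_db <- function(x, ...) {
  cat(sprintf("CeD peptide database '%s': %d peptides (%d native, %d deamidated), %d row(s) rejected\n",
              x$version_label, nrow(x$peptides),
              sum(x$peptides$form == "native"),
              sum(x$peptides$form == "deamidated"),
              x$n_rejected))
  invisible(x)
}

#' Write a peptide database to a delimited table
#'
#' @param db A `ced_peptide_db`.
#' @param file Output path.
#' @param sep Field separator, tab by default.
#' @return Invisibly, `file`.
#' @export
write_peptide_table <- function(db, file, sep = "\t") {
  stopifnot(inherits(db, "ced_peptide_db"))
  utils::write.table(db$peptides, file = file, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# Materialize a path for `file` arguments that may be connections or raw text.
.as_local_file <- function(file) {
  if (inherits(file, "connection")) {
    tmp <- tempfile()
    writeLines(readLines(file), tmp)
    return(tmp)
  }
  if (is.character(file) && length(file) == 1L && !grepl("\n", file) &&
      !startsWith(file, ">") && file.exists(file))
    return(file)
  if (is.character(file)) {
    tmp <- tempfile()
    writeLines(unlist(strsplit(file, "\n", fixed = TRUE)), tmp)
    return(tmp)
  }
  stop("cannot read from object of class ", class(file)[1L], call. = FALSE)
}
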