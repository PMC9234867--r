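#' Alignment configuration
#'
#' Bundles the scoring and statistics parameters for the local-alignment
#' tier. Defaults follow the classic protein-alignment setup of full-length
#' FASTA-style searches: BLOSUM50 with affine gap penalties of -10 (open)
#' and -2 (per residue). The Karlin-Altschul parameters `lambda` and `K`
#' default to documented approximations for gapped BLOSUM50 scores; the
#' resulting expectation values are order-of-magnitude estimates, not
#' bit-exact reproductions of any particular search engine's empirically
#' regressed statistics.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (`"BLOSUM50"`, `"BLOSUM62"`, ...), or a numeric matrix.
#' @param gap_open Gap opening penalty, a non-positive integer. A gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param gap_extend Gap extension penalty per residue, non-positive, with
#'   `gap_open <= gap_extend <= 0`.
#' @param lambda,K Karlin-Altschul statistical parameters; both must be
#'   positive.
#' @return A list of class `ced_align_config`.
#' @export
align_config <- function(matrix = "BLOSUM50", gap_open = -10L,
                         gap_extend = -2L, lambda = 0.090, K = 0.021) {
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("gap penalties must satisfy gap_open <= gap_extend <= 0",
         call. = FALSE)
  if (!is.numeric(lambda) || lambda <= 0 || !is.numeric(K) || K <= 0)
    stop("statistical parameters lambda and K must be positive", call. = FALSE)
  mat <- .resolve_matrix(matrix)
  structure(list(matrix = mat, matrix_name = if (is.character(matrix)) matrix else "custom",
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "ced_align_config")
}

.resolve_matrix <- function(matrix) {
  if (is.matrix(matrix)) {
    if (!isTRUE(all.equal(matrix, t(matrix))))
      stop("substitution matrix must be symmetric", call. = FALSE)
    diagv <- diag(matrix)[intersect(rownames(matrix), AA_ALPHABET20)]
    if (any(diagv <= 0))
      stop("substitution matrix must have positive diagonal for the 20 standard residues",
           call. = FALSE)
    return(matrix)
  }
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Karlin-Altschul expectation value
#'
#' Computes `E = K * m * n * exp(-lambda * S)` for a local alignment raw
#' score `S`, query length `m` and searched size `n`. When a panel is
#' searched, `n` is the total residue count of the panel so that E reflects
#' the expected number of chance hits of at least score S in the whole
#' search, growing linearly with panel size.
#'
#' @param raw_score Non-negative raw alignment score.
#' @param query_len Query length (>= 1).
#' @param subject_len Subject length (>= 1); used as `n` when
#'   `panel_residues` is `NULL`.
#' @param stat_params List with positive elements `lambda` and `K` (e.g. an
#'   [align_config()]).
#' @param panel_residues Optional total residue count of the searched panel.
#' @return The expectation value, a positive real number.
#' @examples
#' cfg <- align_config(lambda = 0.267, K = 0.041)
#' evalue_karlin_altschul(log(0.041 * 290 * 290) / 0.267, 290, 290, cfg)  # 1
#' @export
evalue_karlin_altschul <- function(raw_score, query_len, subject_len,
                                   stat_params = align_config(),
                                   panel_residues = NULL) {
  lambda <- stat_params$lambda
  K <- stat_params$K
  if (is.null(lambda) || is.null(K) || lambda <= 0 || K <= 0)
    stop("configuration error: lambda and K must be positive", call. = FALSE)
  if (raw_score < 0) stop("raw_score must be >= 0", call. = FALSE)
  if (query_len < 1 || subject_len < 1)
    stop("sequence lengths must be >= 1", call. = FALSE)
  n <- if (is.null(panel_residues)) subject_len else panel_residues
  K * query_len * n * exp(-lambda * raw_score)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment under affine gap penalties, with the
#' alignment statistics used by the risk-screening tier: percent identity
#' over all alignment columns (gap columns included), overlap length in
#' columns, gap-column count, aligned spans, and a Karlin-Altschul
#' expectation value.
#'
#' @param query,subject Protein records (as accepted by
#'   [find_exact_matches()]) or bare sequence strings.
#' @param config An [align_config()].
#' @param panel_residues Total residues of the searched panel for the
#'   E-value; defaults to the subject length.
#' @return A one-row data frame of class `ced_alignment` with columns
#'   `query_id`, `subject_id`, `raw_score`, `bit_score`, `identity_pct`,
#'   `overlap_len`, `gap_columns`, `query_start`, `query_end`,
#'   `subject_start`, `subject_end` (1-based closed spans), `e_score`,
#'   `subject_len`, and the aligned strings `query_aln`, `subject_aln`.
#' @export
local_align <- function(query, subject, config = align_config(),
                        panel_residues = NULL) {
  stopifnot(inherits(config, "ced_align_config"))
  q <- .as_single_record(query)
  s <- .as_single_record(subject)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(q$sequence),
    subject = Biostrings::AAString(s$sequence),
    type = "local",
    substitutionMatrix = config$matrix,
    gapOpening = -config$gap_open,
    gapExtension = -config$gap_extend)
  raw <- BiocGenerics::score(aln)
  m <- nchar(q$sequence)
  n_sub <- nchar(s$sequence)

  if (raw <= 0) {
    # degenerate: best local alignment is empty
    e <- evalue_karlin_altschul(0, m, n_sub, config, panel_residues)
    return(.alignment_row(q$id, s$id, 0, config, 0, 0L, 0L,
                          c(0L, -1L), c(0L, -1L), e, n_sub, "", ""))
  }

  qa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  qc <- strsplit(qa, "")[[1]]
  sc <- strsplit(sa, "")[[1]]
  overlap <- length(qc)
  matches <- sum(qc == sc & qc != "-")
  gap_cols <- sum(qc == "-" | sc == "-")
  identity <- 100 * matches / overlap
  e <- evalue_karlin_altschul(raw, m, n_sub, config, panel_residues)
  .alignment_row(q$id, s$id, raw, config, identity, overlap, gap_cols,
                 c(BiocGenerics::start(Biostrings::pattern(aln)),
                   BiocGenerics::end(Biostrings::pattern(aln))),
                 c(BiocGenerics::start(Biostrings::subject(aln)),
                   BiocGenerics::end(Biostrings::subject(aln))),
                 e, n_sub, qa, sa)
}

.alignment_row <- function(query_id, subject_id, raw, config, identity,
                           overlap, gap_cols, qspan, sspan, e, subject_len,
                           qa, sa) {
  out <- data.frame(
    query_id = query_id, subject_id = subject_id,
    raw_score = raw,
    bit_score = (config$lambda * raw - log(config$K)) / log(2),
    identity_pct = identity,
    overlap_len = as.integer(overlap),
    gap_columns = as.integer(gap_cols),
    query_start = as.integer(qspan[1L]), query_end = as.integer(qspan[2L]),
    subject_start = as.integer(sspan[1L]), subject_end = as.integer(sspan[2L]),
    e_score = e,
    subject_len = as.integer(subject_len),
    query_aln = qa, subject_aln = sa,
    stringsAsFactors = FALSE)
  class(out) <- c("ced_alignment", "data.frame")
  out
}

#' Align a query against a representative CeD protein panel
#'
#' Runs [local_align()] of the query against every panel protein, with the
#' E-value scaled to the total residue count of the panel, and returns one
#' result per panel protein sorted by ascending E-value, then descending
#' percent identity, then subject id.
#'
#' @param query Protein record or sequence string.
#' @param panel Data frame of protein records (see [as_protein_records()]).
#' @param config An [align_config()].
#' @return Data frame of alignment rows (class `ced_alignment`).
#' @export
align_panel <- function(query, panel, config = align_config()) {
  panel <- as_protein_records(panel)
  if (nrow(panel) == 0L) stop("panel must be non-empty", call. = FALSE)
  total <- sum(nchar(panel$sequence))
  rows <- lapply(seq_len(nrow(panel)), function(i)
    local_align(query, panel[i, , drop = FALSE], config,
                panel_residues = total))
  out <- do.call(rbind, rows)
  out <- out[order(out$e_score, -out$identity_pct, out$subject_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ced_alignment", "data.frame")
  out
}

#' Expected identity after gap-free substitutions
#'
#' The full-length, gap-free expectation used to sanity-check aligner output
#' on in-silico substituted sequences: substituting `n_substitutions`
#' residues in a protein of length `protein_len` leaves
#' `100 * (protein_len - n_substitutions) / protein_len` percent identity.
#'
#' @param protein_len Protein length in residues.
#' @param n_substitutions Number of substituted residues, between 0 and
#'   `protein_len`.
#' @return Percent identity.
#' @examples
#' identity_after_substitution(290, 13)  # 95.52
#' @export
identity_after_substitution <- function(protein_len, n_substitutions) {
  stopifnot(protein_len >= 1, n_substitutions >= 0,
            n_substitutions <= protein_len)
  100 * (protein_len - n_substitutions) / protein_len
}
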