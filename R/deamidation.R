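#' Find predicted TG2 deamidation sites (QXP rule)
#'
#' Tissue transglutaminase (TG2) preferentially deamidates glutamine (Q) to
#' glutamic acid (E) when the glutamine sits in a QXP configuration, where X
#' is any residue other than proline. This scans a sequence for every such
#' site; overlapping sites are all reported.
#'
#' Coordinates are 1-based: a hit at `start` means `substr(seq, start,
#' start + 2)` matches Q-X-P with X != P.
#'
#' @param seq Canonical amino-acid sequence (see [validate_sequence()]).
#' @return Data frame with columns `start` (1-based index of the Q), `motif`
#'   (the 3-residue window) and `kind` (`"QXP_site"`), in ascending order.
#'   Sequences shorter than 3 residues yield zero rows.
#' @examples
#' find_deamidation_sites("QAP")  # one site at 1
#' find_deamidation_sites("LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF")$start  # 10 17 24
#' @export
find_deamidation_sites <- function(seq) {
  seq <- validate_sequence(seq)
  n <- nchar(seq)
  empty <- data.frame(start = integer(), motif = character(),
                      kind = character(), stringsAsFactors = FALSE)
  if (n < 3L) return(empty)
  ch <- strsplit(seq, "")[[1]]
  i <- seq_len(n - 2L)
  hit <- ch[i] == "Q" & ch[i + 1L] != "P" & ch[i + 2L] == "P"
  starts <- i[hit]
  if (length(starts) == 0L) return(empty)
  data.frame(start = starts,
             motif = substring(seq, starts, starts + 2L),
             kind = "QXP_site", stringsAsFactors = FALSE)
}

#' Apply deamidation at given QXP sites
#'
#' Converts Q to E at exactly the given site starts; every site must be a
#' valid QXP site of `seq` (or already deamidated there, in which case the
#' call is an idempotent no-op for that site). Sequence length is preserved.
#'
#' @param seq Canonical sequence.
#' @param sites Integer vector of 1-based site starts, or a data frame with
#'   a `start` column as returned by [find_deamidation_sites()].
#' @return The deamidated sequence.
#' @examples
#' deamidate("QAP", 1)  # "EAP"
#' @export
deamidate <- function(seq, sites) {
  seq <- validate_sequence(seq)
  if (is.data.frame(sites)) sites <- sites$start
  sites <- as.integer(sites)
  if (length(sites) == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  for (s in sites) {
    if (s < 1L || s > n)
      stop("site ", s, " out of range", call. = FALSE)
    if (s > n - 2L || !(ch[s] %in% c("Q", "E")) || ch[s + 1L] == "P" ||
        ch[s + 2L] != "P")
      stop("position ", s, " is not a QXP deamidation site of the sequence",
           call. = FALSE)
    ch[s] <- "E"
  }
  paste(ch, collapse = "")
}

#' Enumerate predicted deamidated variants
#'
#' Applies every non-empty subset of the QXP deamidation sites of `seq`,
#' yielding up to `2^k - 1` variants for `k` sites, in deterministic order:
#' subsets by increasing size, then lexicographically by site tuple. The
#' plurality of variants mirrors how CeD peptide databases store multiple
#' overlapping native and deamidated peptide forms rather than one fully
#' deamidated sequence.
#'
#' @param seq Canonical sequence.
#' @param max_variants Truncate (with a warning) after this many variants;
#'   guards pathological Q/P-rich inputs. Default 4096.
#' @return Character vector of variant sequences (possibly empty).
#' @examples
#' enumerate_deamidated("QAPQAP")  # "EAPQAP" "QAPEAP" "EAPEAP"
#' @export
enumerate_deamidated <- function(seq, max_variants = 4096L) {
  stopifnot(max_variants >= 1L)
  seq <- validate_sequence(seq)
  sites <- find_deamidation_sites(seq)$start
  k <- length(sites)
  if (k == 0L) return(character())
  total <- 2^k - 1
  subsets <- list()
  for (size in seq_len(k)) {
    # index-based to sidestep combn's scalar-x special case; lexicographic
    combs <- utils::combn(seq_len(k), size, function(ix) sites[ix],
                          simplify = FALSE)
    subsets <- c(subsets, combs)
    if (length(subsets) >= max_variants) break
  }
  if (total > max_variants) {
    warning(sprintf("truncated deamidated variants at %d of %.0f",
                    max_variants, total), call. = FALSE)
    subsets <- subsets[seq_len(max_variants)]
  }
  vapply(subsets, function(s) deamidate(seq, s), character(1L))
}

#' Scan for the EFSA Q/E-X1-P-X2 motif
#'
#' The 2017 EFSA GMO allergenicity guidance proposes a coarse CeD screen
#' based on 4-residue windows whose first position is Q or E and whose third
#' position is P. X1 and X2 are treated as any residue (including proline);
#' the guidance does not constrain them. All overlapping windows are
#' reported.
#'
#' @param seq Canonical sequence (length >= 4 for any hit).
#' @return Data frame with columns `start` (1-based), `motif` (4-mer) and
#'   `kind` (`"EFSA_4mer"`).
#' @examples
#' scan_efsa_motif("QLPY")  # one hit at 1
#' @export
scan_efsa_motif <- function(seq) {
  seq <- validate_sequence(seq)
  n <- nchar(seq)
  empty <- data.frame(start = integer(), motif = character(),
                      kind = character(), stringsAsFactors = FALSE)
  if (n < 4L) return(empty)
  ch <- strsplit(seq, "")[[1]]
  i <- seq_len(n - 3L)
  hit <- ch[i] %in% c("Q", "E") & ch[i + 2L] == "P"
  starts <- i[hit]
  if (length(starts) == 0L) return(empty)
  data.frame(start = starts,
             motif = substring(seq, starts, starts + 3L),
             kind = "EFSA_4mer", stringsAsFactors = FALSE)
}

#' Literature-documented example CeD peptides
#'
#' Three well-characterized gluten peptides used throughout the package's
#' examples and synthetic fixtures: the 33-mer CD4+ T-cell reactive
#' alpha2-gliadin peptide, the 13-residue innate-immunity (toxic) gliadin
#' peptide, and the CD8+ T-cell reactive alpha-gliadin peptide p123-p132.
#'
#' @return Data frame in [peptide_db()] row format.
#' @export
reference_peptides <- function() {
  data.frame(
    sequence = c("LQLQPFPQPQLPYPQPQLPYPQPQLPYPQPQPF",
                 "LGQQQPFPPQQPY",
                 "QLIPCMDVVL"),
    form = "native",
    evidence = c("immunogenic", "toxic", "immunogenic"),
    t_cell = c("CD4", "none", "CD8"),
    references = c("alpha2-gliadin 33-mer", "gliadin p31-43 region 13-mer",
                   "alpha-gliadin p123-p132"),
    stringsAsFactors = FALSE)
}
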