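# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Average composition of globular proteins; used for flanks and unrelated
# sequences. Q and P sit at their background frequencies (~4-5%), far below
# prolamin levels.
.default_composition <- function() {
  c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7, G = 7.1,
    H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9, P = 4.7, S = 6.6,
    T = 5.3, W = 1.1, Y = 2.9, V = 6.9)
}

#' Synthetic sequence generator configuration
#'
#' Controls the deterministic generator of prolamin-like (Q/P-rich,
#' repeat-structured) and unrelated (background-composition) protein
#' sequences used for fixtures and validation panels. With a fixed seed all
#' generator output is byte-identical across runs.
#'
#' @param seed Integer RNG seed.
#' @param repeat_unit Short peptide repeated to form the prolamin-like
#'   repetitive domain; the default `"PQQPFPQQ"` mimics the PQQPFPQQ-type
#'   repeats of gliadins.
#' @param n_repeats Number of (noisy) repeat copies, >= 1.
#' @param flank_len Length of each terminal flank drawn from `composition`.
#' @param sub_rate Per-position substitution rate applied to each repeat
#'   copy (default 0.05).
#' @param composition Named residue-frequency table over the 20 standard
#'   residues for flanks and unrelated sequences.
#' @return A list of class `ced_generator_config`.
#' @export
generator_config <- function(seed = 1L, repeat_unit = "PQQPFPQQ",
                             n_repeats = 30L, flank_len = 20L,
                             sub_rate = 0.05,
                             composition = .default_composition()) {
  stopifnot(n_repeats >= 1L, flank_len >= 0L, sub_rate >= 0, sub_rate <= 1)
  repeat_unit <- validate_sequence(repeat_unit, allow_x = FALSE,
                                   what = "repeat_unit")
  stopifnot(all(names(composition) %in% AA_ALPHABET20),
            length(composition) > 1, all(composition >= 0))
  structure(list(seed = as.integer(seed), repeat_unit = repeat_unit,
                 n_repeats = as.integer(n_repeats),
                 flank_len = as.integer(flank_len),
                 sub_rate = sub_rate,
                 composition = composition / sum(composition)),
            class = "ced_generator_config")
}

.sample_residues <- function(n, composition) {
  if (n == 0L) return(character())
  sample(names(composition), n, replace = TRUE, prob = composition)
}

# Substitute each position independently with probability `rate`, always to
# a different residue.
.mutate_chars <- function(ch, rate, alphabet = AA_ALPHABET20) {
  if (rate <= 0) return(ch)
  flip <- stats::runif(length(ch)) < rate
  for (i in which(flip)) {
    ch[i] <- sample(setdiff(alphabet, ch[i]), 1L)
  }
  ch
}

#' Generate a prolamin-like protein sequence
#'
#' Random terminal flanks around `n_repeats` noisy copies of the repeat
#' unit — the repeat architecture that gives seed-storage prolamins their
#' high glutamine and proline content. With the default configuration the
#' Q+P fraction of the sequence exceeds 0.3.
#'
#' @param config A [generator_config()]; its `seed` determines the output.
#' @param id Record id.
#' @return A one-row protein record data frame.
#' @export
make_prolamin_like <- function(config = generator_config(),
                               id = "prolamin_like") {
  stopifnot(inherits(config, "ced_generator_config"))
  with_seed(config$seed, {
    unit <- strsplit(config$repeat_unit, "")[[1]]
    reps <- unlist(lapply(seq_len(config$n_repeats), function(i)
      .mutate_chars(unit, config$sub_rate)))
    seq <- paste(c(.sample_residues(config$flank_len, config$composition),
                   reps,
                   .sample_residues(config$flank_len, config$composition)),
                 collapse = "")
    data.frame(id = id, description = "synthetic prolamin-like",
               sequence = seq, stringsAsFactors = FALSE)
  })
}

#' Generate an unrelated background protein sequence
#'
#' Residues drawn i.i.d. from the configured composition table — a stand-in
#' for proteins from sources with no CeD association (animals, fungi,
#' microbes).
#'
#' @param length Sequence length, >= 20.
#' @param config A [generator_config()].
#' @param id Record id.
#' @return A one-row protein record data frame.
#' @export
make_unrelated <- function(length, config = generator_config(),
                           id = "unrelated") {
  stopifnot(inherits(config, "ced_generator_config"))
  if (length < 20L) stop("unrelated sequences must be >= 20 residues",
                         call. = FALSE)
  with_seed(config$seed, {
    seq <- paste(.sample_residues(as.integer(length), config$composition),
                 collapse = "")
    data.frame(id = id, description = "synthetic unrelated",
               sequence = seq, stringsAsFactors = FALSE)
  })
}

#' Eliminate all exact peptide matches by greedy substitution
#'
#' Reproduces the in-silico validation procedure that substitutes residues
#' (alanine by default) in a protein until the exact-match tier finds no
#' database peptide. Positions are chosen greedily: at each step the
#' position covered by the most remaining hits is substituted (leftmost on
#' ties), then the protein is re-scanned — so hits newly created by a
#' substitution are also caught. Greedy cover may use more substitutions
#' than the true minimum.
#'
#' @param protein Protein record or sequence string.
#' @param index A `ced_match_index`.
#' @param substitute Replacement residue (default `"A"`); positions already
#'   holding it are replaced with `"G"` instead so every substitution
#'   changes the residue.
#' @param positions Optional integer vector of 1-based positions to
#'   substitute first (e.g. to script a published substitution profile);
#'   greedy ablation then continues only if hits remain.
#' @return List with `record` (mutated protein record, id suffixed
#'   `_ablated`), `n_substitutions`, and `positions` (1-based).
#' @export
ablate_matches <- function(protein, index, substitute = "A",
                           positions = NULL) {
  q <- .as_single_record(protein)
  ch <- strsplit(q$sequence, "")[[1]]
  L <- length(ch)
  done <- integer()
  sub_at <- function(i) {
    ch[i] <<- if (ch[i] == substitute) "G" else substitute
    done <<- c(done, i)
  }
  for (p in as.integer(positions)) {
    if (p < 1L || p > L) stop("substitution position out of range", call. = FALSE)
    sub_at(p)
  }
  cur <- function() data.frame(id = q$id, description = q$description,
                               sequence = paste(ch, collapse = ""),
                               stringsAsFactors = FALSE)
  repeat {
    hits <- find_exact_matches(cur(), index)
    if (nrow(hits) == 0L) break
    if (length(done) >= L)
      stop("unable to ablate all exact matches within ", L,
           " substitutions", call. = FALSE)
    cover <- integer(L)
    for (j in seq_len(nrow(hits))) {
      span <- hits$start[j]:hits$end[j]
      cover[span] <- cover[span] + 1L
    }
    cover[done] <- 0L  # never substitute the same position twice
    sub_at(which.max(cover))
  }
  rec <- cur()
  rec$id <- paste0(q$id, "_ablated")
  list(record = rec, n_substitutions = length(done), positions = sort(done))
}

# Splice `insert` into `seq` so that it occupies positions at..(at+nchar-1).
.plant <- function(seq, insert, at) {
  paste0(substr(seq, 1L, at - 1L), insert,
         substr(seq, at + nchar(insert), nchar(seq)))
}

# Random Q/P-rich peptide in the gliadin repeat grammar, 9-15 residues.
.synthetic_peptide <- function(unit) {
  L <- sample(9:15, 1L)
  base <- strsplit(strtrim(paste(rep(unit, 3L), collapse = ""), L), "")[[1]]
  n_mut <- sample(1:2, 1L)
  for (k in seq_len(n_mut)) {
    i <- sample(length(base), 1L)
    base[i] <- sample(setdiff(AA_ALPHABET20, base[i]), 1L)
  }
  paste(base, collapse = "")
}

#' Build the complete synthetic validation assets
#'
#' Generates, deterministically under one seed, everything needed to run
#' and test the whole screening pipeline without any external download:
#'
#' * a peptide database of 20+ records — the three literature-documented
#'   example peptides ([reference_peptides()]), their predicted deamidated
#'   variants (QXP rule), and planted synthetic Q/P-rich peptides;
#' * a panel of six prolamin-like representative proteins that contain the
#'   planted (and reference) peptides;
#' * four labelled query groups emulating the published validation design:
#'   `group_I` (prolamin-like, contain database peptides),
#'   `group_Ib` (prolamin-like with all exact matches ablated — high panel
#'   identity but no peptide), `group_II` (non-Pooideae-monocot-like
#'   homologs, divergent repeat grammar), `group_III`
#'   (dicot-like, weakly similar), `group_IV` (unrelated background
#'   proteins).
#'
#' @param seed Integer seed; identical seeds rebuild identical assets.
#' @return List with elements `db` (`ced_peptide_db`), `index`
#'   (`ced_match_index`), `panel` (protein records), `queries` (protein
#'   records with a `group` column), and `seed`.
#' @export
make_toy_assets <- function(seed = 1L) {
  refs <- reference_peptides()

  # predicted deamidated forms of the reference peptides
  deam <- do.call(rbind, lapply(seq_len(nrow(refs)), function(i) {
    v <- enumerate_deamidated(refs$sequence[i])
    if (length(v) == 0L) return(NULL)
    data.frame(sequence = v, form = "deamidated",
               evidence = refs$evidence[i], t_cell = refs$t_cell[i],
               references = paste0(refs$references[i], " (predicted deamidated)"),
               stringsAsFactors = FALSE)
  }))

  with_seed(seed, {
    planted <- unique(vapply(1:8, function(j) .synthetic_peptide("PQQPFPQQ"),
                             character(1L)))
    planted_df <- data.frame(sequence = planted, form = "native",
                             evidence = "immunogenic", t_cell = "CD4",
                             references = "synthetic planted peptide",
                             stringsAsFactors = FALSE)
    db <- peptide_db(rbind(refs, deam, planted_df),
                     version_label = sprintf("synthetic-seed%d", seed))
    index <- build_peptide_index(db)

    panel_seeds <- sample.int(1e6, 6L)
    panel <- do.call(rbind, lapply(1:6, function(i) {
      cfg <- generator_config(seed = panel_seeds[i],
                              n_repeats = sample(25:35, 1L))
      rec <- make_prolamin_like(cfg, id = sprintf("ced_rep_%02d", i))
      ins <- if (i == 1L) refs$sequence else
        sample(planted, min(3L, length(planted)))
      for (p in ins) {
        at <- sample(seq_len(max(1L, nchar(rec$sequence) - nchar(p))), 1L)
        rec$sequence <- .plant(rec$sequence, p, at)
      }
      rec$description <- "synthetic representative CeD protein"
      rec
    }))

    # group I: prolamin-like queries that carry at least one database peptide
    group_I <- do.call(rbind, lapply(1:4, function(i) {
      cfg <- generator_config(seed = sample.int(1e6, 1L),
                              n_repeats = sample(20:30, 1L))
      rec <- make_prolamin_like(cfg, id = sprintf("gI_query_%02d", i))
      pep <- sample(db$peptides$sequence, sample(1:2, 1L))
      for (p in pep) {
        at <- sample(seq_len(max(1L, nchar(rec$sequence) - nchar(p))), 1L)
        rec$sequence <- .plant(rec$sequence, p, at)
      }
      rec
    }))

    # group Ib: panel homologs at ~98% identity with every exact match removed
    group_Ib <- do.call(rbind, lapply(1:2, function(i) {
      src <- panel[i + 1L, , drop = FALSE]
      ch <- .mutate_chars(strsplit(src$sequence, "")[[1]], 0.02)
      mut <- data.frame(id = sprintf("gIb_query_%02d", i), description = "",
                        sequence = paste(ch, collapse = ""),
                        stringsAsFactors = FALSE)
      abl <- ablate_matches(mut, index)
      out <- abl$record
      out$id <- sprintf("gIb_query_%02d", i)
      out$description <- "synthetic Pooideae-like, exact matches ablated"
      out
    }))

    # groups II/III: repeat proteins from divergent grammars (zein-like and
    # dicot-prolamin-like); residue overlap with the panel grammar is kept
    # low so panel identity lands below the 45% criterion
    group_II <- do.call(rbind, lapply(1:3, function(i) {
      cfg <- generator_config(seed = sample.int(1e6, 1L),
                              repeat_unit = "MQNSLALANS",
                              n_repeats = sample(20:28, 1L),
                              sub_rate = 0.10)
      make_prolamin_like(cfg, id = sprintf("gII_query_%02d", i))
    }))
    group_III <- do.call(rbind, lapply(1:3, function(i) {
      cfg <- generator_config(seed = sample.int(1e6, 1L),
                              repeat_unit = "SESTVKDWMR",
                              n_repeats = sample(18:24, 1L),
                              sub_rate = 0.15)
      make_prolamin_like(cfg, id = sprintf("gIII_query_%02d", i))
    }))

    group_IV <- do.call(rbind, lapply(1:4, function(i) {
      cfg <- generator_config(seed = sample.int(1e6, 1L))
      make_unrelated(sample(80:400, 1L), cfg,
                     id = sprintf("gIV_query_%02d", i))
    }))

    queries <- rbind(
      cbind(group_I, group = "group_I", stringsAsFactors = FALSE),
      cbind(group_Ib, group = "group_Ib", stringsAsFactors = FALSE),
      cbind(group_II, group = "group_II", stringsAsFactors = FALSE),
      cbind(group_III, group = "group_III", stringsAsFactors = FALSE),
      cbind(group_IV, group = "group_IV", stringsAsFactors = FALSE))
    rownames(queries) <- NULL

    list(db = db, index = index, panel = panel, queries = queries,
         seed = as.integer(seed))
  })
}
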