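data(BLOSUM50, package = "Biostrings")

test_that("identity cases and simple substitutions score as expected", {
  set.seed(51)
  s <- random_aa(20)
  a <- local_align(s, s)
  expect_equal(a$identity_pct, 100)
  expect_identical(a$overlap_len, 20L)
  expect_identical(a$gap_columns, 0L)
  # self-alignment score is the sum of diagonal matrix scores
  expect_equal(a$raw_score,
               sum(BLOSUM50[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])]))

  b <- local_align("QAP", "QCP")
  expect_equal(b$identity_pct, 100 * 2 / 3, tolerance = 1e-12)
  expect_identical(b$overlap_len, 3L)

  expect_error(local_align("", "QAP"), "empty")
})

test_that("alignment scores equal the brute-force affine-gap DP oracle", {
  set.seed(52)
  cfg <- align_config()
  for (trial in 1:200) {
    a <- random_aa(sample(1:30, 1))
    b <- random_aa(sample(1:30, 1))
    got <- local_align(a, b, cfg)$raw_score
    want <- sw_score_oracle(a, b, BLOSUM50, cfg$gap_open, cfg$gap_extend)
    expect_equal(got, want, info = paste(a, b))
  }
  # also under different gap penalties
  cfg2 <- align_config(gap_open = -14L, gap_extend = -4L)
  for (trial in 1:40) {
    a <- random_aa(sample(5:30, 1))
    b <- random_aa(sample(5:30, 1))
    expect_equal(local_align(a, b, cfg2)$raw_score,
                 sw_score_oracle(a, b, BLOSUM50, -14, -4),
                 info = paste(a, b))
  }
})

test_that("alignment score is symmetric with spans swapped", {
  set.seed(53)
  for (trial in 1:30) {
    a <- random_aa(sample(10:40, 1))
    b <- random_aa(sample(10:40, 1))
    ab <- local_align(a, b)
    ba <- local_align(b, a)
    # the optimal score is direction-invariant; the reported alignment may
    # differ between directions when several tracebacks tie
    expect_equal(ab$raw_score, ba$raw_score)
    expect_identical(ab$query_end - ab$query_start,
                     nchar(gsub("-", "", ab$query_aln)) - 1L)
    expect_identical(ab$subject_end - ab$subject_start,
                     nchar(gsub("-", "", ab$subject_aln)) - 1L)
  }
})

test_that("E-value follows the Karlin-Altschul closed form", {
  cfg <- align_config(lambda = 0.267, K = 0.041)
  # lambda * S = ln(K m n)  =>  E = 1
  S <- log(0.041 * 290 * 290) / 0.267
  expect_equal(evalue_karlin_altschul(S, 290, 290, cfg), 1.0, tolerance = 1e-12)
  # S = 0 => E = K m n; monotone decreasing in S; linear in panel size
  expect_equal(evalue_karlin_altschul(0, 100, 200, cfg), 0.041 * 100 * 200)
  e1 <- evalue_karlin_altschul(50, 100, 200, cfg)
  e2 <- evalue_karlin_altschul(60, 100, 200, cfg)
  expect_lt(e2, e1)
  expect_equal(evalue_karlin_altschul(50, 100, 200, cfg, panel_residues = 4000),
               2 * evalue_karlin_altschul(50, 100, 200, cfg, panel_residues = 2000))
  expect_lt(evalue_karlin_altschul(1e4, 100, 200, cfg), 1e-300)  # S -> Inf
  expect_error(align_config(lambda = -1), "positive")
  expect_error(evalue_karlin_altschul(10, 100, 200, list(lambda = 0, K = 0.1)),
               "configuration error")
})

test_that("align_panel ranks by E-value and handles degenerate compositions", {
  assets <- toy_assets()
  panel <- assets$panel
  # query identical to one panel member ranks it first at 100% identity
  q <- panel[3, , drop = FALSE]
  q$id <- "copy_of_3"
  res <- align_panel(q, panel)
  expect_identical(nrow(res), nrow(panel))
  expect_identical(res$subject_id[1], panel$id[3])
  expect_equal(res$identity_pct[1], 100)
  expect_true(!is.unsorted(res$e_score))
  # poly-alanine query: no large E-value alignment passes the criteria
  polyA <- paste(rep("A", 13), collapse = "")
  resA <- align_panel(polyA, panel)
  expect_true(all(resA$e_score > 1))
  expect_false(any(alignment_meets_criteria(resA$identity_pct, resA$e_score,
                                            resA$overlap_len)))
  # panel of one
  expect_identical(nrow(align_panel(q, panel[1, , drop = FALSE])), 1L)
})

test_that("substituted sequences realign at the predicted identity with no gaps", {
  expect_equal(identity_after_substitution(290, 13), 95.52, tolerance = 1e-3)
  expect_equal(identity_after_substitution(290, 11), 96.21, tolerance = 1e-3)
  expect_equal(identity_after_substitution(123, 0), 100)

  set.seed(54)
  # low-repeat background sequence: identity within one column of (L-k)/L
  L <- 200
  s <- random_aa(L)
  ch <- strsplit(s, "")[[1]]
  pos <- sample(L, 9)
  for (i in pos) ch[i] <- setdiff(c("A", "G"), ch[i])[1]
  mut <- paste(ch, collapse = "")
  a <- local_align(mut, s)
  expect_identical(a$gap_columns, 0L)
  expect_gte(a$identity_pct, identity_after_substitution(L, 9) - 100 / L)

  # repeat-rich prolamin-like original: assert the one-sided bound
  p <- make_prolamin_like(generator_config(seed = 55), id = "p")
  Lp <- nchar(p$sequence)
  chp <- strsplit(p$sequence, "")[[1]]
  posp <- sample(Lp, 10)
  for (i in posp) chp[i] <- setdiff(c("W", "H"), chp[i])[1]
  mutp <- data.frame(id = "mut", description = "", sequence = paste(chp, collapse = ""))
  ap <- local_align(mutp, p)
  expect_gte(ap$identity_pct, identity_after_substitution(Lp, 10) - 1)
})
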