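test_that("generator is deterministic under seed and sensitive to it", {
  cfg <- generator_config(seed = 7)
  p1 <- make_prolamin_like(cfg)
  p2 <- make_prolamin_like(cfg)
  expect_identical(p1, p2)
  p3 <- make_prolamin_like(generator_config(seed = 8))
  expect_false(identical(p1$sequence, p3$sequence))
  u1 <- make_unrelated(100, generator_config(seed = 9))
  expect_identical(u1, make_unrelated(100, generator_config(seed = 9)))
  expect_identical(nchar(u1$sequence), 100L)
  expect_error(make_unrelated(19, cfg), ">= 20")
})

test_that("prolamin-like sequences are Q/P-rich; noiseless single repeat is the unit", {
  p <- make_prolamin_like(generator_config(seed = 1, n_repeats = 30))
  ch <- strsplit(p$sequence, "")[[1]]
  expect_gt(mean(ch %in% c("Q", "P")), 0.3)
  bare <- make_prolamin_like(generator_config(seed = 1, n_repeats = 1,
                                              flank_len = 0, sub_rate = 0))
  expect_identical(bare$sequence, "PQQPFPQQ")
})

test_that("greedy ablation removes every exact match and reports positions", {
  assets <- toy_assets()
  # protein equal to a single database peptide: one substitution suffices
  one <- build_peptide_index(peptide_db(data.frame(
    sequence = PEP10, form = "native", evidence = "immunogenic")))
  abl <- ablate_matches(c(p = PEP10), one)
  expect_identical(abl$n_substitutions, 1L)
  expect_identical(nrow(find_exact_matches(abl$record, one)), 0L)

  one33 <- build_peptide_index(peptide_db(data.frame(
    sequence = PEP33, form = "native", evidence = "immunogenic")))
  expect_identical(ablate_matches(c(p = PEP33), one33)$n_substitutions, 1L)

  # prolamin-like fixture with planted, overlapping peptides
  panel1 <- assets$panel[1, , drop = FALSE]
  abl2 <- ablate_matches(panel1, assets$index)
  expect_identical(nrow(find_exact_matches(abl2$record, assets$index)), 0L)
  expect_identical(length(abl2$positions), abl2$n_substitutions)
  L <- nchar(panel1$sequence)
  expect_gte(identity_after_substitution(L, abl2$n_substitutions), 90)
  # substituted record differs from the original exactly at the positions
  d <- which(strsplit(abl2$record$sequence, "")[[1]] !=
               strsplit(panel1$sequence, "")[[1]])
  expect_identical(d, abl2$positions)
})

test_that("scripted substitution profiles are honored before greedy ablation", {
  idx <- build_peptide_index(peptide_db(data.frame(
    sequence = PEP10, form = "native", evidence = "immunogenic")))
  abl <- ablate_matches(c(p = PEP10), idx, positions = c(2L, 5L))
  expect_identical(abl$positions, c(2L, 5L))
  expect_identical(substring(abl$record$sequence, 2, 2), "A")
  expect_identical(nrow(find_exact_matches(abl$record, idx)), 0L)
})

test_that("toy assets regenerate identically under one seed", {
  a1 <- make_toy_assets(123)
  a2 <- make_toy_assets(123)
  expect_identical(a1$db$peptides, a2$db$peptides)
  expect_identical(a1$panel, a2$panel)
  expect_identical(a1$queries, a2$queries)
  expect_false(identical(make_toy_assets(124)$queries$sequence,
                         a1$queries$sequence))
})

test_that("toy assets satisfy their construction contract", {
  assets <- toy_assets()
  expect_gte(nrow(assets$db$peptides), 20)
  expect_gte(nrow(assets$panel), 5)
  expect_true(all(c("group_I", "group_Ib", "group_II", "group_III", "group_IV")
                  %in% assets$queries$group))
  # every deamidated database record carries at least one E
  deam <- assets$db$peptides[assets$db$peptides$form == "deamidated", ]
  expect_true(all(grepl("E", deam$sequence)))
  # group I queries all contain a database peptide; group IV none do
  gI <- assets$queries[assets$queries$group == "group_I", ]
  expect_true(all(vapply(gI$sequence, contains_ced_peptide, logical(1),
                         index = assets$index)))
  gIV <- assets$queries[assets$queries$group == "group_IV", ]
  expect_false(any(vapply(gIV$sequence, contains_ced_peptide, logical(1),
                          index = assets$index)))
  # group Ib was ablated: no exact hits by construction
  gIb <- assets$queries[assets$queries$group == "group_Ib", ]
  expect_false(any(vapply(gIb$sequence, contains_ced_peptide, logical(1),
                          index = assets$index)))
})

test_that("unrelated queries almost never reach the alignment criteria", {
  assets <- toy_assets()
  set.seed(61)
  n_flagged <- 0L
  for (i in 1:100) {
    u <- make_unrelated(sample(80:300, 1),
                        generator_config(seed = sample.int(1e6, 1)),
                        id = sprintf("u%03d", i))
    res <- align_panel(u, assets$panel)
    if (any(alignment_meets_criteria(res$identity_pct, res$e_score,
                                     res$overlap_len)))
      n_flagged <- n_flagged + 1L
  }
  expect_lte(n_flagged, 5L)  # >= 95% classified no_significant_similarity
})
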