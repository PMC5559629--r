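test_that("percent identity behaves on elementary cases", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)
  expect_equal(pairwise_identity("NNNN", "NNNN"), 0)   # N never matches
  expect_equal(pairwise_identity("ACGT", "TGCA"),
               pairwise_identity("TGCA", "ACGT"))
  expect_error(pairwise_identity("", "ACGT"), "nonempty")
  expect_error(pairwise_identity("ACGU", "ACGT"), "outside")
  expect_error(alignment_scoring(gap_open = 1), "negative")
})

test_that("identity matches an independent dynamic-programming aligner", {
  set.seed(73)
  for (i in 1:25) {
    a <- random_seq(sample(40:60, 1), with_n = i %% 5 == 0)
    b <- random_seq(sample(40:60, 1), with_n = i %% 5 == 0)
    got <- pairwise_identity(a, b)
    orc <- r_nw_identity(a, b)
    expect_identical(got, orc$identity)
  }
})

test_that("alignment scores equal the Biostrings global aligner", {
  mat <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(mat) <- 2
  set.seed(79)
  for (i in 1:15) {
    a <- random_seq(sample(40:70, 1))
    b <- random_seq(sample(40:70, 1))
    score <- rumherit:::.nw_align_pairs(a, b, 2, -1, -5, -2)$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat, gapOpening = 5,
      gapExtension = 2, scoreOnly = TRUE)
    expect_equal(score, ref)
  }
})

test_that("identity is invariant under joint reverse-complement", {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  set.seed(83)
  for (i in 1:8) {
    a <- random_seq(50); b <- random_seq(55)
    expect_equal(pairwise_identity(a, b),
                 pairwise_identity(rc(a), rc(b)))
  }
})

test_that("mean pairwise similarity averages all unordered pairs", {
  # three length-10 sequences with pairwise identities 90, 80, 70
  s1 <- "AAAAAAAAAA"
  s2 <- "CAAAAAAAAA"              # 1 mismatch to s1  -> 90
  s3 <- "AGGAAAAAAA"              # 2 mismatches to s1 -> 80; 3 to s2 -> 70
  ss <- sequence_set(c(a = s1, b = s2, c = s3))
  expect_equal(pairwise_identity(s1, s2), 90)
  expect_equal(pairwise_identity(s1, s3), 80)
  expect_equal(pairwise_identity(s2, s3), 70)
  expect_equal(mean_pairwise_similarity(ss, c("a", "b", "c")), 80)
  expect_equal(mean_pairwise_similarity(ss, c("a", "a", "b")), 90)
  expect_error(mean_pairwise_similarity(ss, "a"), "at least two")
  expect_error(mean_pairwise_similarity(ss, c("a", "zz")), "absent")
})

test_that("the random-subset null detects a planted clade", {
  spec <- planted_microbiome(n_otus = 150, n_heritable = 12,
                             clade_identity = 0.9,
                             background_identity = 0.75, seed = 89)
  s <- simulate_sequences(spec)
  nul <- similarity_null_test(s, spec$heritable_ids, spec$otu_ids,
                              n_draws = 60, seed = 90)
  expect_lte(nul$p_value, 1 / 61 + 1e-12)
  expect_equal(length(nul$null_means), 60L)
  expect_gt(nul$observed, max(nul$null_means))
  # determinism and the add-one convention (p never zero)
  nul2 <- similarity_null_test(s, spec$heritable_ids, spec$otu_ids,
                               n_draws = 60, seed = 90)
  expect_identical(nul$null_means, nul2$null_means)
  expect_gt(nul$p_value, 0)
  # degenerate pool: heritable set equals the eligible pool -> p = 1
  sub <- sequence_set(s$seqs[spec$heritable_ids])
  deg <- similarity_null_test(sub, spec$heritable_ids, spec$heritable_ids,
                              n_draws = 10, seed = 1)
  expect_equal(deg$p_value, 1)
})

test_that("the null p shrinks as the planted identity gap grows", {
  ps <- vapply(c(0.80, 0.86, 0.93), function(ci) {
    spec <- planted_microbiome(n_otus = 80, n_heritable = 10,
                               clade_identity = ci,
                               background_identity = 0.75, seed = 91)
    s <- simulate_sequences(spec)
    similarity_null_test(s, spec$heritable_ids, spec$otu_ids,
                         n_draws = 40, seed = 92)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_lte(ps[3], 1 / 41 + 1e-12)
})

test_that("taxon enrichment matches hypergeometric enumeration", {
  taxo <- setNames(rep(c("d;p;c;OrdA;f;g", "d;p;c;OrdB;f;g"), c(30, 70)),
                   sprintf("o%03d", 1:100))
  her <- names(taxo)[c(1:8, 31:32)]   # 8 of 10 heritable in OrdA
  enr <- taxon_enrichment(taxo, her, rank = "order")
  rowA <- enr[enr$taxon == "OrdA", ]
  expect_equal(rowA$heritable_in, 8L)
  expect_equal(rowA$other_in, 22L)
  expect_equal(rowA$p_value, fisher_oracle(8, 2, 22, 68),
               tolerance = 1e-12)
  expect_equal(rowA$odds_ratio, (8 / 2) / (22 / 68))
  # extreme table: all heritable in one taxon
  taxo2 <- setNames(rep(c("d;p;c;X;f;g", "d;p;c;Y;f;g"), c(5, 15)),
                    paste0("q", 1:20))
  enr2 <- taxon_enrichment(taxo2, paste0("q", 1:5), rank = "order")
  rowX <- enr2[enr2$taxon == "X", ]
  expect_equal(rowX$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(rowX$odds_ratio, Inf)
  # unparseable lineages count as unclassified
  taxo3 <- setNames(c("d;p", "d;p;c;OrdA;f;g"), c("u1", "u2"))
  expect_equal(taxon_at_rank(taxo3, "order"),
               c("unclassified", "OrdA"), ignore_attr = TRUE)
  enr3 <- taxon_enrichment(taxo3, "u2", rank = "order")
  expect_true("unclassified" %in% enr3$taxon)
})

test_that("null heritable draws give well-calibrated enrichment p-values", {
  set.seed(93)
  taxo <- setNames(
    paste0("d;p;c;", sample(rep(c("A", "B", "C"), c(40, 35, 25))), ";f;g"),
    sprintf("n%03d", 1:100))
  ps <- replicate(60, {
    her <- sample(names(taxo), 10)
    min(taxon_enrichment(taxo, her, rank = "order")$p_value)
  })
  # minimum over 3 taxa: conservative, but gross miscalibration would show
  expect_gt(mean(ps), 0.15)
  expect_lt(mean(ps < 0.01), 0.1)
})
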