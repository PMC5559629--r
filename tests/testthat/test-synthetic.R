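test_that("herd designs validate their structure", {
  expect_error(herd_design(n_animals = 10, n_genotyped = 20), "<=")
  expect_error(herd_design(families = rep(10L, 6), n_genotyped = 47),
               "exceed")
  expect_error(herd_design(maf_range = c(0, 0.5)), "maf_range")
  expect_error(herd_design(missing_rate = 1), "missing_rate")
})

test_that("zero missing rate yields complete calls; fixed seeds reproduce", {
  d <- herd_design(n_animals = 20, n_genotyped = 15,
                   families = c(3L, 2L), n_snps = 200, missing_rate = 0,
                   seed = 41)
  sim <- simulate_genotypes(d)
  expect_false(anyNA(sim$genotypes$calls))
  expect_equal(dim(sim$genotypes$calls), c(15L, 200L))
  # byte-identical PED/MAP under the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  g1 <- withr::local_tempfile(); g2 <- withr::local_tempfile()
  write_plink(simulate_genotypes(d)$genotypes, f1, g1)
  write_plink(simulate_genotypes(d)$genotypes, f2, g2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(g1), readLines(g2))
  # pedigree expectation: 1 diagonal, 0.25 within families, 0 elsewhere
  P <- sim$pedigree$A
  expect_equal(unname(diag(P)), rep(1, 20))
  expect_equal(P[1, 2], 0.25)   # family of 3: animals 1-3
  expect_equal(P[4, 5], 0.25)   # family of 2: animals 4-5
  expect_equal(P[1, 4], 0)
  expect_equal(P[16, 17], 0)    # non-genotyped cohort animals unrelated
})

test_that("half-sib pairs average 0.25 relatedness in the realized GRM", {
  means <- vapply(1:5, function(seed) {
    d <- herd_design(n_animals = 100, n_genotyped = 100,
                     families = c(4L, 3L, rep(2L, 9L)), n_snps = 3000,
                     maf_range = c(0.3, 0.5), missing_rate = 0, seed = seed)
    sim <- simulate_genotypes(d)
    a <- compute_grm(sim$genotypes)
    ped <- sim$pedigree$A
    pairs <- which(ped == 0.25 & upper.tri(ped), arr.ind = TRUE)
    mean(a$A[pairs])
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.25), 0.05)
})

test_that("abundance samples are simplex-normalized with planted structure", {
  d <- herd_design(n_animals = 50, n_genotyped = 40, families = rep(4L, 10),
                   n_snps = 600, missing_rate = 0, seed = 43)
  sim <- simulate_genotypes(d)
  spec <- planted_microbiome(n_otus = 80, n_heritable = 8, seed = 44)
  ab <- simulate_abundances(sim$pedigree, spec)
  expect_lt(max(abs(colSums(ab$values) - 1)), 1e-9)
  expect_true(all(ab$values >= 0))
  expect_equal(nrow(ab$values), 80L)
  expect_equal(ncol(ab$values), 50L * 3L)
  # presence fractions are honored (nonzero in the day-invariant sense)
  present <- vapply(unique(ab$samples$animal), function(an)
    rowSums(ab$values[, ab$samples$animal == an, drop = FALSE]) > 0,
    logical(80))
  frac <- rowMeans(present)
  expect_equal(unname(round(frac * 50) / 50),
               unname(round(spec$presence_profile * 50) / 50),
               tolerance = 0.03)
  # determinism
  ab2 <- simulate_abundances(sim$pedigree, spec)
  expect_identical(ab2$values, ab$values)
})

test_that("without planted signal, abundance similarity ignores kinship", {
  cors <- vapply(1:20, function(seed) {
    d <- herd_design(n_animals = 40, n_genotyped = 40,
                     families = rep(4L, 10), n_snps = 300,
                     missing_rate = 0, seed = seed)
    sim <- simulate_genotypes(d)
    spec <- planted_microbiome(n_otus = 60, n_heritable = 0, true_h2 = 0,
                               seed = seed + 100)
    ab <- simulate_abundances(sim$pedigree, spec)
    M <- animal_abundance(ab)
    S <- cor(M)
    ut <- upper.tri(S)
    cor(S[ut], sim$pedigree$A[ut])
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("planted heritability survives the abundance map", {
  d <- herd_design(n_animals = 200, n_genotyped = 200,
                   families = rep(5L, 40), n_snps = 2500,
                   missing_rate = 0, seed = 47)
  sim <- simulate_genotypes(d)
  a <- compute_grm(sim$genotypes)
  spec <- planted_microbiome(n_otus = 150, n_heritable = 15, true_h2 = 0.8,
                             seed = 48)
  spec$presence_profile[spec$heritable_ids] <- 1
  ab <- simulate_abundances(embed_relatedness(a, sim$pedigree$ids$iid), spec)
  d1 <- ab$values[spec$heritable_ids, ab$samples$day == 1]
  anim <- ab$samples$animal[ab$samples$day == 1]
  Y <- t(d1[, match(a$ids$iid, anim)])
  fit <- reml_fit_batch(Y, eigen_prepare(a))
  expect_lt(abs(mean(fit$h2) - 0.8), 0.15)
})

test_that("sequence sets honor the planted clade structure", {
  spec <- planted_microbiome(n_otus = 40, n_heritable = 6,
                             clade_identity = 1, background_identity = 0.75,
                             seed = 51)
  s <- simulate_sequences(spec)
  expect_equal(length(unique(s$seqs[spec$heritable_ids])), 1L)
  expect_false(any(grepl("[^ACGT]", s$seqs)))
  expect_true(all(nchar(s$seqs) == 250L))
  # identity targets are approximately met
  spec2 <- planted_microbiome(n_otus = 60, n_heritable = 10,
                              clade_identity = 0.9,
                              background_identity = 0.75, seed = 52)
  s2 <- simulate_sequences(spec2)
  within <- mean_pairwise_similarity(s2, spec2$heritable_ids)
  bg <- mean_pairwise_similarity(
    s2, setdiff(spec2$otu_ids, spec2$heritable_ids)[1:12])
  expect_lt(abs(within - 90), 3)
  expect_lt(abs(bg - 75), 4)
  expect_error(planted_microbiome(clade_identity = 0.7,
                                  background_identity = 0.75),
               "exceed")
  # heritable clade enriched for one order
  ord <- taxon_at_rank(spec2$taxonomy[spec2$heritable_ids], "order")
  expect_gte(mean(ord == "Bacteroidales"), 0.5)
})

test_that("trait linkage produces the requested monotone relationships", {
  d <- herd_design(n_animals = 30, n_genotyped = 30, families = rep(3L, 10),
                   n_snps = 300, missing_rate = 0, seed = 53)
  sim <- simulate_genotypes(d)
  spec <- planted_microbiome(n_otus = 20, n_heritable = 2, seed = 54)
  spec$presence_profile[] <- 1   # avoid zero-abundance rank ties
  ab <- simulate_abundances(sim$pedigree, spec)
  M <- animal_abundance(ab)
  otu <- spec$heritable_ids[1]
  lk_pos <- trait_linkage(list(idx = setNames(1, otu)), noise_sd = 1e-12,
                          seed = 55)
  lk_neg <- trait_linkage(list(idx = setNames(-1, otu)), noise_sd = 1e-12,
                          seed = 55)
  tr_pos <- simulate_traits(ab, lk_pos)
  tr_neg <- simulate_traits(ab, lk_neg)
  expect_equal(cor(M[otu, tr_pos$animal], tr_pos$idx, method = "spearman"),
               1)
  expect_equal(cor(M[otu, tr_neg$animal], tr_neg$idx, method = "spearman"),
               -1)
  expect_error(simulate_traits(ab, trait_linkage(
    list(idx = c(nosuch = 1)), noise_sd = 1, seed = 1)), "unknown OTU")
  # noise far above the effect washes the correlation out
  rs <- vapply(1:30, function(s) {
    lk <- trait_linkage(list(idx = setNames(1, otu)),
                        noise_sd = 1000 * sd(M[otu, ]), seed = s)
    tr <- simulate_traits(ab, lk)
    cor(M[otu, tr$animal], tr$idx, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})
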