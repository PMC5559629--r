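mk_table <- function(n_otus = 6, animals = sprintf("c%02d", 1:12),
                     days = 1:3, seed = 95) {
  set.seed(seed)
  samples <- data.frame(
    sample_id = paste0(rep(animals, each = length(days)), "_d", days),
    animal = rep(animals, each = length(days)),
    day = rep(days, length(animals)))
  vals <- matrix(runif(n_otus * nrow(samples), 0, 1 / n_otus / 2),
                 n_otus, nrow(samples))
  abundance_table(vals, data.frame(otu_id = paste0("otu", seq_len(n_otus)),
                                   taxonomy = "t"), samples)
}

test_that("per-animal abundance is the available-case day mean", {
  tb <- mk_table()
  M <- animal_abundance(tb)
  o <- vapply(colnames(M), function(an)
    rowMeans(tb$values[, tb$samples$animal == an, drop = FALSE]),
    numeric(nrow(tb$values)))
  expect_equal(M, matrix(o, nrow(M), dimnames = dimnames(M)))
  # explicit means: (0.1, 0.2, 0.3) -> 0.2, and (0.1, 0.3) -> 0.2
  tb$values[1, tb$samples$animal == "c01"] <- c(0.1, 0.2, 0.3)
  expect_equal(animal_abundance(tb)["otu1", "c01"], 0.2)
  tb2 <- mk_table(days = 1:2)
  tb2$values[1, tb2$samples$animal == "c01"] <- c(0.1, 0.3)
  expect_equal(animal_abundance(tb2)["otu1", "c01"], 0.2)
})

test_that("Spearman profiles match the average-rank Pearson oracle", {
  set.seed(97)
  M <- matrix(runif(5 * 30), 5, 30,
              dimnames = list(paste0("otu", 1:5), sprintf("c%02d", 1:30)))
  M[2, ] <- round(M[2, ], 1)               # heavy ties
  traits <- data.frame(animal = colnames(M),
                       up = seq_len(30),
                       tied = round(rnorm(30), 0),
                       noisy = rnorm(30))
  prof <- spearman_profile(M, traits)
  for (i in seq_len(nrow(prof))) {
    x <- M[prof$otu_id[i], ]
    y <- traits[[prof$index[i]]]
    expect_equal(prof$r[i], spearman_oracle(x, y), tolerance = 1e-12)
  }
  # monotone and antitone extremes
  M2 <- rbind(mono = sort(runif(30)))
  colnames(M2) <- traits$animal
  p2 <- spearman_profile(M2, traits)
  expect_equal(p2$r[p2$index == "up"], 1)
  traits$down <- rev(seq_len(30))
  p3 <- spearman_profile(M2, traits)
  expect_equal(p3$r[p3$index == "down"], -1)
  # invariance under strictly monotone transforms
  traits$logup <- log(traits$up)
  p4 <- spearman_profile(M2, traits)
  expect_equal(p4$r[p4$index == "logup"], p4$r[p4$index == "up"])
  # constant vectors are recorded as missing with a reason
  traits$flat <- 5
  p5 <- spearman_profile(M2, traits)
  expect_true(is.na(p5$r[p5$index == "flat"]))
  expect_equal(p5$reason[p5$index == "flat"], "constant")
})

test_that("mean-correlation permutation null flags planted indices", {
  set.seed(101)
  n_an <- 60
  M <- matrix(runif(10 * n_an), 10, n_an,
              dimnames = list(paste0("otu", 1:10), sprintf("c%02d", 1:n_an)))
  traits <- data.frame(animal = colnames(M),
                       planted = as.numeric(M[1, ])^2,   # monotone, no noise
                       null = rnorm(n_an))
  nul <- mean_correlation_null(M, traits, n_perm = 999, seed = 103)
  s <- nul$summary
  expect_lte(s$p_mean_abs_r[s$index == "planted"], 0.002)
  expect_gt(s$p_mean_abs_r[s$index == "null"], 0.05)
  # determinism
  nul2 <- mean_correlation_null(M, traits, n_perm = 999, seed = 103)
  expect_identical(nul$null_abs, nul2$null_abs)
  expect_error(mean_correlation_null(M, traits, n_perm = 0), "n_perm")
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(107)
  n_an <- 40
  ps <- replicate(50, {
    M <- matrix(runif(6 * n_an), 6, n_an,
                dimnames = list(paste0("o", 1:6), paste0("c", 1:n_an)))
    traits <- data.frame(animal = colnames(M), idx = rnorm(n_an))
    mean_correlation_null(M, traits, n_perm = 79,
                          seed = sample.int(1e6, 1))$summary$p_mean_abs_r
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lte(mean(ps <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 50))
})

test_that("group comparison of |r| detects shifts and skips singletons", {
  set.seed(109)
  mk_prof <- function(her_mu, oth_mu) {
    data.frame(
      otu_id = c(paste0("h", 1:22), paste0("n", 1:400)),
      index = "idx",
      r = c(pmin(1, rnorm(22, her_mu, 0.1)), pmin(1, rnorm(400, oth_mu, 0.1))),
      p_value = 0.5, n = 50, reason = NA)
  }
  shifted <- mean_abs_corr_compare(mk_prof(0.5, 0.2), paste0("h", 1:22))
  expect_lt(shifted$p_value, 0.05)
  expect_gt(shifted$mean_abs_r_heritable, shifted$mean_abs_r_other)
  # exchangeable groups reject at roughly the nominal rate
  rej <- replicate(100, {
    prof <- mk_prof(0.3, 0.3)
    mean_abs_corr_compare(prof, paste0("h", 1:22))$p_value < 0.05
  })
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
  # singleton group is skipped with a warning
  prof <- mk_prof(0.3, 0.3)
  expect_warning(out <- mean_abs_corr_compare(prof, "h1"), "fewer than 2")
  expect_equal(nrow(out), 0L)
})

test_that("correlation odds ratios follow the 2x2 formula with Fisher p", {
  prof <- data.frame(
    otu_id = c(paste0("h", 1:22), paste0("n", 1:1000)),
    index = "idx",
    p_value = c(rep(0.01, 10), rep(0.5, 12), rep(0.01, 100), rep(0.5, 900)),
    r = 0.1, n = 50, reason = NA)
  er <- correlation_odds_ratio(prof, paste0("h", 1:22))
  expect_equal(c(er$hc, er$hn, er$nc, er$nn), c(10L, 12L, 100L, 900L))
  expect_equal(er$odds_ratio, (10 / 12) / (100 / 900))  # = 7.5
  expect_equal(er$odds_ratio, 7.5)
  expect_equal(er$fisher_p, fisher_oracle(10, 12, 100, 900),
               tolerance = 1e-12)
  # balanced table
  prof2 <- data.frame(otu_id = c("h1", "h2", "n1", "n2"), index = "idx",
                      p_value = c(0.01, 0.5, 0.01, 0.5), r = 0, n = 50,
                      reason = NA)
  expect_equal(correlation_odds_ratio(prof2, c("h1", "h2"))$odds_ratio, 1)
  # infinite and missing-p handling: NA p counts as not correlated
  prof3 <- data.frame(otu_id = c("h1", "h2", "n1", "n2"), index = "idx",
                      p_value = c(0.01, 0.01, NA, 0.5), r = 0, n = 50,
                      reason = NA)
  expect_equal(correlation_odds_ratio(prof3, c("h1", "h2"))$odds_ratio, Inf)
})

test_that("odds ratios above one pair with smaller one-sided p", {
  set.seed(113)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 20) + 1L, 2)
    orat <- (tab[1, 1] / tab[1, 2]) / (tab[2, 1] / tab[2, 2])
    if (abs(log(orat)) < 0.2) next
    p_gr <- fisher.test(tab, alternative = "greater")$p.value
    p_tr <- fisher.test(t(tab)[2:1, 2:1],
                        alternative = "greater")$p.value
    if (orat > 1) expect_lte(p_gr, p_tr + 1e-12)
  }
})

test_that("presence-abundance correlation reuses the Spearman machinery", {
  set.seed(115)
  M <- matrix(runif(8 * 20), 8, 20,
              dimnames = list(paste0("o", 1:8), paste0("c", 1:20)))
  # zero out increasing numbers of animals so presence orders the sums
  for (o in 1:8) M[o, seq_len(2 * (o - 1))] <- 0
  M <- M * rep(2^(8:1), times = 20)[1:8]  # scale so sums follow presence
  pa <- presence_abundance_correlation(M)
  expect_equal(pa$r, spearman_oracle(pa$presence, pa$abundance_sum))
  # strict monotone construction gives r = 1
  M2 <- matrix(0, 5, 10, dimnames = list(paste0("o", 1:5), paste0("c", 1:10)))
  for (o in 1:5) M2[o, seq_len(o + 3)] <- o
  pa2 <- presence_abundance_correlation(M2)
  expect_equal(pa2$r, 1)
  expect_error(presence_abundance_correlation(M2[1:2, ]), "three")
  # permuting the presence/sum pairing across OTUs kills the correlation
  set.seed(117)
  pres <- pa$presence
  rs <- replicate(100, spearman_oracle(pres, sample(pa$abundance_sum)))
  expect_lt(abs(mean(rs)), 0.15)
})
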