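#' Per-animal abundance matrix
#'
#' Collapses the day replicates: each animal's value is the mean of its
#' available day samples (missing days are excluded from the mean). Used
#' for all correlation analyses; heritability fits stay per-day.
#'
#' @param t an [abundance_table()].
#' @return Numeric matrix, OTUs in rows, animals in columns.
#' @export
animal_abundance <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  animals <- unique(t$samples$animal)
  counts <- table(t$samples$animal)[animals]
  if (any(counts == 0)) {
    warning("animals without samples excluded: ",
            paste(animals[counts == 0], collapse = ", "))
    animals <- animals[counts > 0]
  }
  out <- vapply(animals, function(a) {
    rowMeans(t$values[, t$samples$animal == a, drop = FALSE])
  }, numeric(nrow(t$values)))
  out <- matrix(out, nrow = nrow(t$values),
                dimnames = list(t$otus$otu_id, animals))
  out
}

# Spearman rank correlation on the pairwise-complete observations, with the
# two-sided p-value from the large-sample t approximation
# t = r * sqrt((n - 2) / (1 - r^2)). Constant vectors give r = NA with a
# reason.
.spearman <- function(x, y, min_n = 10L) {
  use <- !is.na(x) & !is.na(y)
  n <- sum(use)
  if (n < min_n)
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "too_few"))
  x <- x[use]; y <- y[use]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "constant"))
  r <- cor(x, y, method = "spearman")
  if (is.na(r)) return(list(r = NA_real_, p = NA_real_, n = n,
                            reason = "undefined"))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n, reason = NA_character_)
}

#' Spearman correlation profile of OTUs against trait indices
#'
#' Correlates every OTU's per-animal abundance with every index over the
#' animals that have both values (pairwise-complete), using Spearman rank
#' correlation with average ranks for ties and a two-sided p-value from the
#' large-sample t approximation.
#'
#' @param abund OTU x animal matrix from [animal_abundance()].
#' @param traits trait data frame (`animal` column plus numeric indices).
#' @param min_n minimum shared animals per pair (default 10).
#' @return Long data frame: `otu_id`, `index`, `r`, `p_value`, `n`,
#'   `reason` (why `r` is missing, when it is).
#' @export
spearman_profile <- function(abund, traits, min_n = 10L) {
  if (colnames(traits)[1L] != "animal")
    stop("trait table must start with an 'animal' column")
  shared <- intersect(colnames(abund), traits$animal)
  if (!length(shared)) stop("no shared animals between abundances and traits")
  A <- abund[, shared, drop = FALSE]
  idx_names <- colnames(traits)[-1L]
  rows <- vector("list", nrow(A) * length(idx_names))
  k <- 0L
  for (idx in idx_names) {
    yv <- traits[[idx]][match(shared, traits$animal)]
    for (o in seq_len(nrow(A))) {
      s <- .spearman(A[o, ], yv, min_n = min_n)
      k <- k + 1L
      rows[[k]] <- data.frame(otu_id = rownames(A)[o], index = idx,
                              r = s$r, p_value = s$p, n = s$n,
                              reason = s$reason, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Permutation null for the mean correlation of heritable OTUs
#'
#' The observed statistic per index is the mean over heritable OTUs of the
#' signed Spearman r, and the mean of |r|. In each of `n_perm` iterations
#' every OTU's abundance profile is independently shuffled across animals
#' and the statistics are recomputed. Empirical p-values use the add-one
#' convention: for the signed mean the test is on its magnitude,
#' `p = (1 + #{|null| >= |observed|}) / (n_perm + 1)`; for the mean |r| it
#' is one-sided on the value itself.
#'
#' @param abund OTU x animal matrix restricted to the heritable OTUs.
#' @param traits trait data frame.
#' @param n_perm iterations (default 1000).
#' @param seed integer seed.
#' @param min_n minimum shared animals per pair.
#' @return An object of class `correlation_null`: data frame `summary`
#'   (per index: `mean_r`, `mean_abs_r`, `p_mean_r`, `p_mean_abs_r`, `n`)
#'   plus the null matrices.
#' @export
mean_correlation_null <- function(abund, traits, n_perm = 1000L, seed = 1L,
                                  min_n = 10L) {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  if (nrow(abund) < 2L) stop("need at least two heritable OTUs")
  shared <- intersect(colnames(abund), traits$animal)
  A <- abund[, shared, drop = FALSE]
  idx_names <- colnames(traits)[-1L]
  trait_cols <- lapply(idx_names, function(idx)
    traits[[idx]][match(shared, traits$animal)])
  names(trait_cols) <- idx_names

  stat_for <- function(M) {
    vapply(idx_names, function(idx) {
      y <- trait_cols[[idx]]
      ok <- !is.na(y)
      if (sum(ok) < min_n) return(c(NA_real_, NA_real_))
      r <- suppressWarnings(
        as.numeric(cor(t(M[, ok, drop = FALSE]), y[ok],
                       method = "spearman")))
      c(mean(r, na.rm = TRUE), mean(abs(r), na.rm = TRUE))
    }, numeric(2))
  }

  obs <- stat_for(A)
  set.seed(seed)
  null_mean <- matrix(NA_real_, n_perm, length(idx_names),
                      dimnames = list(NULL, idx_names))
  null_abs <- null_mean
  n_anim <- ncol(A)
  for (it in seq_len(n_perm)) {
    P <- A
    for (o in seq_len(nrow(A))) P[o, ] <- A[o, sample.int(n_anim)]
    s <- stat_for(P)
    null_mean[it, ] <- s[1L, ]
    null_abs[it, ] <- s[2L, ]
  }
  p_mean <- vapply(seq_along(idx_names), function(j)
    (1 + sum(abs(null_mean[, j]) >= abs(obs[1L, j]), na.rm = TRUE)) /
      (n_perm + 1), numeric(1))
  p_abs <- vapply(seq_along(idx_names), function(j)
    (1 + sum(null_abs[, j] >= obs[2L, j], na.rm = TRUE)) / (n_perm + 1),
    numeric(1))
  n_used <- vapply(idx_names, function(idx)
    sum(!is.na(trait_cols[[idx]])), numeric(1))
  structure(list(
    summary = data.frame(index = idx_names, mean_r = obs[1L, ],
                         mean_abs_r = obs[2L, ], p_mean_r = p_mean,
                         p_mean_abs_r = p_abs, n = n_used,
                         stringsAsFactors = FALSE, row.names = NULL),
    null_mean = null_mean, null_abs = null_abs,
    n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "correlation_null")
}

#' @export
print.correlation_null <- function(x, ...) {
  cat("correlation_null over", x$n_perm, "permutations:\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Compare mean |r| of heritable OTUs against the rest of the microbiome
#'
#' Per index, a Welch two-sample t-test of the |Spearman r| values of the
#' heritable OTUs against those of all other eligible OTUs. Indices where
#' either group has fewer than two usable values are skipped with a
#' warning.
#'
#' @param profile long correlation data frame from [spearman_profile()]
#'   computed over all eligible OTUs.
#' @param heritable_ids the heritable OTU ids.
#' @return Data frame per tested index: group means, t statistic, p-value,
#'   group sizes.
#' @export
mean_abs_corr_compare <- function(profile, heritable_ids) {
  heritable_ids <- as.character(heritable_ids)
  rows <- list()
  for (idx in unique(profile$index)) {
    sub <- profile[profile$index == idx & !is.na(profile$r), , drop = FALSE]
    g_her <- abs(sub$r[sub$otu_id %in% heritable_ids])
    g_oth <- abs(sub$r[!(sub$otu_id %in% heritable_ids)])
    if (length(g_her) < 2L || length(g_oth) < 2L) {
      warning("index ", idx, " skipped: a group has fewer than 2 members")
      next
    }
    tt <- t.test(g_her, g_oth)
    rows[[idx]] <- data.frame(
      index = idx, mean_abs_r_heritable = mean(g_her),
      mean_abs_r_other = mean(g_oth), t_statistic = unname(tt$statistic),
      p_value = tt$p.value, n_heritable = length(g_her),
      n_other = length(g_oth), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(index = character(), mean_abs_r_heritable = numeric(),
                      mean_abs_r_other = numeric(), t_statistic = numeric(),
                      p_value = numeric(), n_heritable = integer(),
                      n_other = integer())
  rownames(out) <- NULL
  out
}

#' OTU correlation odds ratio per index
#'
#' An OTU counts as correlated with an index when its nominal Spearman
#' p-value is below `alpha`; a missing correlation counts as not
#' correlated. Per index the 2x2 counts are hc/hn (heritable OTUs
#' correlated / not) and nc/nn (non-heritable correlated / not); the odds
#' ratio is `(hc/hn) / (nc/nn)`, infinite when `hn * nc = 0` with
#' `hc * nn > 0` and undefined (NA) when a full margin is empty. The
#' two-sided Fisher exact p accompanies each table, and the Bonferroni flag
#' marks `p < 0.05 / number of indices tested`.
#'
#' @param profile long correlation data frame from [spearman_profile()]
#'   over all eligible OTUs.
#' @param heritable_ids the heritable OTU ids.
#' @param alpha nominal threshold (default 0.05).
#' @return Data frame per index: `hc`, `hn`, `nc`, `nn`, `odds_ratio`,
#'   `fisher_p`, `bonferroni_significant`.
#' @export
correlation_odds_ratio <- function(profile, heritable_ids, alpha = 0.05) {
  heritable_ids <- as.character(heritable_ids)
  idx_names <- unique(profile$index)
  if (!nrow(profile)) stop("no eligible OTUs in the correlation profile")
  rows <- lapply(idx_names, function(idx) {
    sub <- profile[profile$index == idx, , drop = FALSE]
    her <- sub$otu_id %in% heritable_ids
    corr <- !is.na(sub$p_value) & sub$p_value < alpha
    hc <- sum(her & corr); hn <- sum(her & !corr)
    nc <- sum(!her & corr); nn <- sum(!her & !corr)
    orat <- if (hc + hn == 0L || nc + nn == 0L) NA_real_
            else if (hn > 0L && nc > 0L) (hc / hn) / (nc / nn)
            else if (hc > 0L && nn > 0L) Inf else NA_real_
    data.frame(index = idx, hc = hc, hn = hn, nc = nc, nn = nn,
               odds_ratio = orat,
               fisher_p = fisher.test(matrix(c(hc, hn, nc, nn), 2L,
                                             byrow = TRUE))$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_significant <- out$fisher_p < 0.05 / nrow(out)
  out
}

#' Presence-abundance correlation of the heritable OTUs
#'
#' Across the heritable OTUs, the Spearman correlation between the number
#' of animals carrying each OTU and its total abundance over animals.
#'
#' @param abund OTU x animal matrix restricted to the heritable OTUs (at
#'   least three).
#' @return List with `r`, `p_value`, `n`, and the per-OTU `presence` and
#'   `abundance_sum` vectors.
#' @export
presence_abundance_correlation <- function(abund) {
  if (nrow(abund) < 3L) stop("need at least three heritable OTUs")
  presence <- rowSums(abund > 0)
  sums <- rowSums(abund)
  if (length(unique(presence)) < 2L)
    return(list(r = NA_real_, p_value = NA_real_, n = nrow(abund),
                presence = presence, abundance_sum = sums,
                reason = "constant presence counts"))
  s <- .spearman(presence, sums, min_n = 3L)
  list(r = s$r, p_value = s$p, n = nrow(abund), presence = presence,
       abundance_sum = sums, reason = s$reason)
}
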