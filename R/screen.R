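#' Presence filter
#'
#' Keeps OTUs detected in at least `min_present` genotyped animals before
#' any heritability testing. By default an animal counts as present when the
#' OTU is nonzero in at least one of its day samples (presence is an
#' animal-level notion, matching the unit of genotyping);
#' `presence = "day"` instead requires nonzero abundance in every day
#' sample.
#'
#' @param t an [abundance_table()].
#' @param genotyped_ids animal ids of the genotyped subset.
#' @param min_present minimum number of genotyped animals (default 12).
#' @param presence `"animal"` (default) or `"day"`.
#' @return The filtered [abundance_table()].
#' @export
presence_filter <- function(t, genotyped_ids, min_present = 12L,
                            presence = c("animal", "day")) {
  stopifnot(inherits(t, "abundance_table"))
  presence <- match.arg(presence)
  genotyped_ids <- as.character(genotyped_ids)
  if (!all(genotyped_ids %in% t$samples$animal))
    stop("genotyped ids absent from the abundance table: ",
         paste(setdiff(genotyped_ids, t$samples$animal), collapse = ", "))
  if (min_present > length(genotyped_ids))
    stop("min_present (", min_present, ") exceeds the number of genotyped ",
         "animals (", length(genotyped_ids), ")")
  sub <- t$values[, t$samples$animal %in% genotyped_ids, drop = FALSE]
  anim <- t$samples$animal[t$samples$animal %in% genotyped_ids]
  nz <- sub > 0
  per_animal <- vapply(genotyped_ids, function(a) {
    cols <- anim == a
    if (presence == "animal") rowSums(nz[, cols, drop = FALSE]) > 0
    else rowSums(nz[, cols, drop = FALSE]) == sum(cols)
  }, logical(nrow(sub)))
  counts <- rowSums(matrix(per_animal, nrow = nrow(sub)))
  keep <- counts >= min_present
  abundance_table(t$values[keep, , drop = FALSE],
                  t$otus[keep, , drop = FALSE], t$samples)
}

# Build one phenotype matrix (animals x OTUs) per day, aligned to the GRM's
# animal order. Days where some GRM animal lacks a sample are still usable:
# the affected animals are reported so the caller can subset.
.day_matrices <- function(t, grm_ids) {
  days <- sort(unique(t$samples$day))
  lapply(days, function(d) {
    cols <- t$samples$day == d
    anim <- t$samples$animal[cols]
    V <- t$values[, cols, drop = FALSE]
    idx <- match(grm_ids, anim)
    present <- !is.na(idx)
    Y <- t(V[, idx[present], drop = FALSE])
    rownames(Y) <- grm_ids[present]
    list(day = d, Y = Y, animals = grm_ids[present])
  })
}

#' Three-day consensus heritability screen
#'
#' For every OTU and sampling day the phenotype is that day's relative
#' abundance across the genotyped animals; each (OTU, day) gets a REML fit
#' against the GRM and a boundary LRT p-value. The consensus heritable set
#' contains the OTUs with `h2 > h2_min` and `p < alpha` on every sampling
#' day. Fits that fail (zero variance, too few animals) exclude the OTU
#' from the consensus. All fits for one animal set share one
#' eigendecomposition of the GRM.
#'
#' @param t a presence-filtered [abundance_table()].
#' @param a a [relatedness_matrix()] over the genotyped animals.
#' @param h2_min heritability threshold (default 0.7; the consensus demands
#'   strictly greater).
#' @param alpha significance threshold (default 0.05, strictly smaller).
#' @param min_animals minimum animals for a fit (default 10).
#' @return An object of class `screen_result`: `consensus` (character ids),
#'   `results` (per-OTU-per-day data frame), `thresholds`.
#' @export
screen_heritable <- function(t, a, h2_min = 0.7, alpha = 0.05,
                             min_animals = 10L) {
  stopifnot(inherits(t, "abundance_table"),
            inherits(a, "relatedness_matrix"))
  grm_ids <- as.character(a$ids$iid)
  dms <- .day_matrices(t, grm_ids)
  res <- list()
  caches <- list()
  for (dm in dms) {
    if (length(dm$animals) < min_animals) {
      res[[length(res) + 1L]] <- data.frame(
        otu_id = t$otus$otu_id, day = dm$day, sigma_u2 = NA_real_,
        sigma_e2 = NA_real_, h2 = NA_real_, lr_statistic = NA_real_,
        p_value = NA_real_, n_used = length(dm$animals), converged = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    key <- paste(dm$animals, collapse = "\r")
    if (is.null(caches[[key]])) {
      idx <- match(dm$animals, grm_ids)
      caches[[key]] <- eigen_prepare(a$A[idx, idx, drop = FALSE])
    }
    fit <- reml_fit_batch(dm$Y, caches[[key]])
    res[[length(res) + 1L]] <- data.frame(
      otu_id = t$otus$otu_id, day = dm$day, sigma_u2 = fit$sigma_u2,
      sigma_e2 = fit$sigma_e2, h2 = fit$h2, lr_statistic = fit$lr_statistic,
      p_value = fit$p_value, n_used = fit$n_used, converged = fit$converged,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  consensus <- .consensus_from_results(results, h2_min, alpha)
  structure(list(consensus = consensus, results = results,
                 thresholds = c(h2_min = h2_min, alpha = alpha,
                                min_animals = min_animals)),
            class = "screen_result")
}

.consensus_from_results <- function(results, h2_min, alpha) {
  pass <- results$converged & !is.na(results$h2) & results$h2 > h2_min &
    !is.na(results$p_value) & results$p_value < alpha
  n_days <- length(unique(results$day))
  tab <- tapply(pass, results$otu_id, function(x) sum(x) == n_days &&
                  length(x) == n_days)
  sort(names(tab)[tab])
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", length(x$consensus), "consensus heritable OTUs of",
      length(unique(x$results$otu_id)), "screened (h2 >",
      x$thresholds["h2_min"], ", p <", x$thresholds["alpha"],
      "on all days)\n")
  invisible(x)
}

#' Permutation false-discovery calibration of the consensus screen
#'
#' Each iteration draws one permutation of the genotyped-animal labels,
#' applies it to the GRM rows and columns (consistently across all OTUs and
#' all days), reruns the full three-day consensus screen, and records the
#' number of OTUs called heritable. The report compares the observed count
#' to the permuted counts via the fraction of permutations with a strictly
#' smaller count.
#'
#' @inheritParams screen_heritable
#' @param n_perm number of iterations (default 100).
#' @param seed integer seed.
#' @return An object of class `permutation_fdr`: `observed`, `perm_counts`,
#'   `fraction_below`, `n_perm`, `seed`.
#' @export
permutation_fdr <- function(t, a, n_perm = 100L, seed = 1L, h2_min = 0.7,
                            alpha = 0.05, min_animals = 10L) {
  stopifnot(inherits(t, "abundance_table"),
            inherits(a, "relatedness_matrix"))
  if (n_perm < 1L) stop("n_perm must be at least 1")
  grm_ids <- as.character(a$ids$iid)
  dms <- .day_matrices(t, grm_ids)
  usable <- vapply(dms, function(dm) length(dm$animals) >= min_animals,
                   TRUE)
  dms <- dms[usable]
  if (!length(dms)) stop("no sampling day has enough animals")
  caches <- list()
  for (i in seq_along(dms)) {
    key <- paste(dms[[i]]$animals, collapse = "\r")
    if (is.null(caches[[key]])) {
      idx <- match(dms[[i]]$animals, grm_ids)
      caches[[key]] <- eigen_prepare(a$A[idx, idx, drop = FALSE])
    }
    dms[[i]]$key <- key
  }
  n_days_total <- length(unique(t$samples$day))

  count_for <- function(perms) {
    pass_all <- NULL
    for (dm in dms) {
      cache <- caches[[dm$key]]
      perm <- perms[[dm$key]]
      fit <- reml_fit_batch(dm$Y, cache, perm = perm)
      pass <- fit$converged & !is.na(fit$h2) & fit$h2 > h2_min &
        !is.na(fit$p_value) & fit$p_value < alpha
      pass_all <- if (is.null(pass_all)) pass else pass_all & pass
    }
    if (length(dms) < n_days_total) return(0L)
    sum(pass_all)
  }

  identity_perms <- lapply(caches, function(c) NULL)
  observed <- count_for(identity_perms)

  set.seed(seed)
  perm_counts <- integer(n_perm)
  for (it in seq_len(n_perm)) {
    perms <- lapply(caches, function(cache) sample.int(cache$n))
    perm_counts[it] <- count_for(perms)
  }
  structure(list(observed = observed, perm_counts = perm_counts,
                 fraction_below = mean(perm_counts < observed),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permutation_fdr")
}

#' @export
print.permutation_fdr <- function(x, ...) {
  cat(sprintf(
    "permutation_fdr: observed %d heritable OTUs; %.0f%% of %d permutations below observed\n",
    x$observed, 100 * x$fraction_below, x$n_perm))
  invisible(x)
}

#' Heritability of host traits
#'
#' One REML fit and boundary LRT per trait column, restricted to genotyped
#' animals with non-missing values for that trait. Traits with fewer than
#' `min_animals` usable animals or zero variance are skipped with a
#' warning.
#'
#' @param traits trait data frame (`animal` column plus numeric indices).
#' @param a a [relatedness_matrix()] over the genotyped animals.
#' @param min_animals minimum usable animals per trait (default 10).
#' @return Data frame with one row per fitted trait: `trait`, `sigma_u2`,
#'   `sigma_e2`, `h2`, `lr_statistic`, `p_value`, `n_used`.
#' @export
trait_heritability <- function(traits, a, min_animals = 10L) {
  stopifnot(inherits(a, "relatedness_matrix"))
  if (colnames(traits)[1L] != "animal")
    stop("trait table must start with an 'animal' column")
  grm_ids <- as.character(a$ids$iid)
  rows <- list()
  for (idx in colnames(traits)[-1L]) {
    y <- traits[[idx]][match(grm_ids, traits$animal)]
    use <- !is.na(y)
    if (sum(use) < min_animals) {
      warning("trait ", idx, " skipped: only ", sum(use),
              " genotyped animals with values")
      next
    }
    if (var(y[use]) == 0) {
      warning("trait ", idx, " skipped: zero variance")
      next
    }
    sub <- which(use)
    fit <- reml_fit(y[sub], a$A[sub, sub, drop = FALSE])
    rows[[idx]] <- data.frame(
      trait = idx, sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2,
      h2 = fit$h2, lr_statistic = fit$lr_statistic, p_value = fit$p_value,
      n_used = fit$n_used, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(trait = character(), sigma_u2 = numeric(),
                      sigma_e2 = numeric(), h2 = numeric(),
                      lr_statistic = numeric(), p_value = numeric(),
                      n_used = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
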