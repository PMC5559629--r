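#' Alignment scoring parameters
#'
#' Scoring for the global pairwise alignments behind the percent-identity
#' statistic. Defaults: match +2, mismatch -1, gap open -5, gap extend -2
#' (a gap run of length L scores `open + L * extend`, so a single-column
#' gap costs 7). `N` scores as a mismatch against everything and never
#' counts as a matched column. The scoring is recorded in the outputs
#' because percent identities from progressive aligners are
#' parameter-dependent.
#'
#' @param match,mismatch,gap_open,gap_extend numeric scores; gap penalties
#'   must be negative, `match` must exceed `mismatch`.
#' @return An object of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 2, mismatch = -1, gap_open = -5,
                              gap_extend = -2) {
  if (gap_open >= 0 || gap_extend >= 0)
    stop("gap penalties must be negative")
  if (match <= mismatch) stop("match score must exceed mismatch score")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "alignment_scoring")
}

.check_seq <- function(s, what) {
  if (length(s) != 1L || is.na(s) || !nzchar(s))
    stop(what, " must be a single nonempty sequence")
  if (grepl("[^ACGTN]", s))
    stop(what, " contains symbols outside A, C, G, T, N")
  s
}

#' Percent identity of two sequences under global alignment
#'
#' Aligns the two sequences end to end (Needleman-Wunsch with affine gaps)
#' and returns `100 * matched columns / alignment columns`; gap columns
#' count in the denominator. Symmetric in its arguments.
#'
#' @param seq_a,seq_b nucleotide strings over A, C, G, T, N.
#' @param scoring an [alignment_scoring()].
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b, scoring = alignment_scoring()) {
  .check_seq(seq_a, "seq_a"); .check_seq(seq_b, "seq_b")
  r <- .nw_align_pairs(seq_a, seq_b, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  100 * r$matches / r$columns
}

# identity for many pairs at once (vectors of equal length)
.identity_many <- function(a, b, scoring) {
  r <- .nw_align_pairs(a, b, scoring$match, scoring$mismatch,
                       scoring$gap_open, scoring$gap_extend)
  100 * r$matches / r$columns
}

#' Mean pairwise similarity of an OTU set
#'
#' Mean percent identity over all unordered pairs within `ids`.
#'
#' @param s a [sequence_set()].
#' @param ids at least two ids present in `s`.
#' @param scoring an [alignment_scoring()].
#' @return Mean percent identity.
#' @export
mean_pairwise_similarity <- function(s, ids,
                                     scoring = alignment_scoring()) {
  stopifnot(inherits(s, "sequence_set"))
  ids <- unique(as.character(ids))
  if (length(ids) < 2L) stop("need at least two ids")
  missing_ids <- setdiff(ids, names(s$seqs))
  if (length(missing_ids))
    stop("ids absent from the sequence set: ",
         paste(missing_ids, collapse = ", "))
  pairs <- combn(ids, 2L)
  mean(.identity_many(s$seqs[pairs[1L, ]], s$seqs[pairs[2L, ]], scoring))
}

#' Random-subset null test for the similarity of the heritable set
#'
#' Compares the mean pairwise 16S identity of the heritable OTUs with the
#' identities of random subsets of the same size drawn (without
#' replacement, uniformly) from the pool of eligible OTUs — the OTUs that
#' passed the presence filter. The empirical p-value uses the add-one
#' convention, `p = (1 + #{null >= observed}) / (n_draws + 1)`, so it is
#' never zero.
#'
#' @param s a [sequence_set()].
#' @param heritable_ids the consensus heritable OTU ids.
#' @param eligible_ids the eligible pool (must contain the heritable ids
#'   and be strictly larger).
#' @param n_draws number of random subsets (default 100).
#' @param seed integer seed.
#' @param scoring an [alignment_scoring()].
#' @return An object of class `similarity_null`: `observed`, `null_means`,
#'   `p_value`, `n_draws`, `subset_size`, `seed`, `scoring`.
#' @export
similarity_null_test <- function(s, heritable_ids, eligible_ids,
                                 n_draws = 100L, seed = 1L,
                                 scoring = alignment_scoring()) {
  stopifnot(inherits(s, "sequence_set"))
  heritable_ids <- unique(as.character(heritable_ids))
  eligible_ids <- unique(as.character(eligible_ids))
  if (!all(heritable_ids %in% eligible_ids))
    stop("heritable ids must be a subset of the eligible pool")
  if (!all(eligible_ids %in% names(s$seqs)))
    stop("eligible ids missing from the sequence set")
  if (length(eligible_ids) < length(heritable_ids))
    stop("the eligible pool cannot be smaller than the heritable set")
  m <- length(heritable_ids)
  if (m < 2L) stop("need at least two heritable OTUs")
  observed <- mean_pairwise_similarity(s, heritable_ids, scoring)
  set.seed(seed)
  null_means <- vapply(seq_len(n_draws), function(i) {
    mean_pairwise_similarity(s, sample(eligible_ids, m), scoring)
  }, numeric(1))
  structure(list(observed = observed, null_means = null_means,
                 p_value = (1 + sum(null_means >= observed)) / (n_draws + 1),
                 n_draws = as.integer(n_draws), subset_size = m,
                 seed = as.integer(seed), scoring = scoring),
            class = "similarity_null")
}

#' @export
print.similarity_null <- function(x, ...) {
  cat(sprintf(
    "similarity_null: observed mean identity %.1f%% vs %d random size-%d subsets (null mean %.1f%%), p = %.4g\n",
    x$observed, x$n_draws, x$subset_size, mean(x$null_means), x$p_value))
  invisible(x)
}

.rank_index <- c(domain = 1L, phylum = 2L, class = 3L, order = 4L,
                 family = 5L, genus = 6L)

#' Extract one taxonomic rank from lineage strings
#' @param taxonomy character vector of `domain;phylum;...;genus` lineages.
#' @param rank one of domain, phylum, class, order, family, genus.
#' @return Character vector of taxa; unparseable lineages give
#'   `"unclassified"`.
#' @export
taxon_at_rank <- function(taxonomy, rank = "order") {
  idx <- .rank_index[[match.arg(rank, names(.rank_index))]]
  parts <- strsplit(as.character(taxonomy), ";", fixed = TRUE)
  out <- vapply(parts, function(p) {
    if (length(p) >= idx && nzchar(trimws(p[idx]))) trimws(p[idx])
    else "unclassified"
  }, "")
  out
}

#' Taxon enrichment of the heritable set
#'
#' For every taxon observed at the requested rank among the eligible OTUs,
#' builds the 2x2 table (heritable vs not) x (taxon vs not) and computes a
#' two-sided Fisher exact p-value, asking whether any taxon contributes
#' more OTUs to the heritable set than its share of the eligible pool
#' predicts.
#'
#' @param taxonomy named character vector of lineage strings for all
#'   eligible OTUs (names are OTU ids).
#' @param heritable_ids the heritable OTU ids.
#' @param rank taxonomic rank to test (default `"order"`).
#' @return Data frame: `taxon`, `heritable_in`, `heritable_out`,
#'   `other_in`, `other_out`, `odds_ratio`, `p_value`, sorted by p.
#' @export
taxon_enrichment <- function(taxonomy, heritable_ids, rank = "order") {
  if (is.null(names(taxonomy))) stop("taxonomy must be named by OTU id")
  heritable_ids <- as.character(heritable_ids)
  if (!all(heritable_ids %in% names(taxonomy)))
    stop("heritable ids missing from the taxonomy")
  taxa <- taxon_at_rank(taxonomy, rank)
  her <- names(taxonomy) %in% heritable_ids
  rows <- lapply(sort(unique(taxa)), function(tx) {
    a <- sum(her & taxa == tx); b <- sum(her & taxa != tx)
    c_ <- sum(!her & taxa == tx); d <- sum(!her & taxa != tx)
    orat <- if (b > 0 && c_ > 0) (a / b) / (c_ / d)
            else if (a > 0 && d > 0) Inf else NA_real_
    data.frame(taxon = tx, heritable_in = a, heritable_out = b,
               other_in = c_, other_out = d, odds_ratio = orat,
               p_value = fisher.test(matrix(c(a, b, c_, d), 2L,
                                            byrow = TRUE))$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value), , drop = FALSE]
}
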