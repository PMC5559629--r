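#' Relatedness matrix container
#'
#' Symmetric matrix of pairwise genetic relationship estimates together with
#' the number of SNPs that informed each pair (pairs with missing calls use
#' only the SNPs observed in both animals).
#'
#' @param A symmetric numeric matrix of relationship estimates.
#' @param ids data frame with columns `fid` and `iid`, one row per animal in
#'   row order of `A`.
#' @param n_pairs symmetric integer matrix of per-pair SNP counts, or a
#'   single count recycled to all pairs.
#' @return An object of class `relatedness_matrix`.
#' @export
relatedness_matrix <- function(A, ids, n_pairs) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (max(abs(A - t(A))) > 1e-12) stop("A must be symmetric (tol 1e-12)")
  if (nrow(ids) != n) stop("ids must have one row per animal")
  if (length(n_pairs) == 1L) n_pairs <- matrix(as.integer(n_pairs), n, n)
  n_pairs <- as.matrix(n_pairs)
  storage.mode(n_pairs) <- "integer"
  if (!all(dim(n_pairs) == n)) stop("n_pairs dimensions must match A")
  if (any(n_pairs < 1L)) stop("every defined pair needs >= 1 SNP")
  dimnames(A) <- list(ids$iid, ids$iid)
  structure(list(A = A, ids = ids, n_pairs = n_pairs),
            class = "relatedness_matrix")
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat("relatedness_matrix:", nrow(x$A), "animals; mean diagonal",
      signif(mean(diag(x$A)), 4), "\n")
  invisible(x)
}

#' @export
dim.relatedness_matrix <- function(x) dim(x$A)

#' Reference-allele frequencies
#'
#' Per-SNP frequency of the "1"-coded reference allele,
#' `p_i = sum(calls) / (2 * non-missing count)`. SNPs fixed at 0 or 1 are
#' flagged monomorphic; [compute_grm()] excludes them.
#'
#' @param g a [genotype_matrix()].
#' @return A list with `p` (named numeric vector) and `monomorphic`
#'   (character vector of fixed SNP ids).
#' @export
allele_frequencies <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  nn <- colSums(!is.na(calls))
  if (any(nn == 0L))
    stop("SNP ", colnames(calls)[which(nn == 0L)[1L]],
         " has no non-missing calls")
  p <- colSums(calls, na.rm = TRUE) / (2 * nn)
  names(p) <- colnames(calls)
  list(p = p, monomorphic = names(p)[p <= 0 | p >= 1])
}

#' Compute the genetic relationship matrix
#'
#' For animals j and k the estimate is the allele-sharing sum weighted by
#' allele rareness,
#' `A_jk = (1/n) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`,
#' where the sum runs over the SNPs observed in both animals and `n` is that
#' pair's count. Equivalently, with complete data, `A = W W' / n` for the
#' column-standardized genotype matrix `W`. The default diagonal applies the
#' same formula with j = k; `diagonal_mode = "gcta"` instead uses
#' `A_jj = 1 + (1/n) * sum_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) /
#' (2 p_i (1 - p_i))`, the convention of the GCTA toolkit.
#'
#' @param g a [genotype_matrix()]; should already have passed QC.
#' @param freqs optional result of [allele_frequencies()]; recomputed from
#'   `g` when `NULL`. Supplying frequencies from a larger reference panel is
#'   supported.
#' @param diagonal_mode `"uniform"` (one formula for all entries, the default)
#'   or `"gcta"`.
#' @return A [relatedness_matrix()].
#' @export
compute_grm <- function(g, freqs = NULL,
                        diagonal_mode = c("uniform", "gcta")) {
  stopifnot(inherits(g, "genotype_matrix"))
  diagonal_mode <- match.arg(diagonal_mode)
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  p <- freqs$p[colnames(g$calls)]
  if (anyNA(p)) stop("frequencies missing for some SNPs in g")
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic SNPs available for the GRM")
  x <- g$calls[, keep, drop = FALSE]
  p <- p[keep]
  n_ind <- nrow(x)

  denom <- sqrt(2 * p * (1 - p))
  z <- sweep(sweep(x, 2L, 2 * p, `-`), 2L, denom, `/`)
  obs <- !is.na(z)
  z[!obs] <- 0
  storage.mode(z) <- "double"
  S <- tcrossprod(z)
  np <- tcrossprod(obs * 1)
  off <- np == 0 & !diag(TRUE, n_ind)
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1L, ]
    stop("animals ", rownames(x)[idx[1L]], " and ", rownames(x)[idx[2L]],
         " share no non-missing SNPs")
  }
  A <- S / pmax(np, 1L)

  if (diagonal_mode == "gcta") {
    # (x^2 - (1 + 2p) x + 2 p^2) / (2 p (1 - p)), averaged over non-missing
    w <- 2 * p * (1 - p)
    num <- x^2 - sweep(x, 2L, 1 + 2 * p, `*`)
    num <- sweep(num, 2L, 2 * p^2, `+`)
    num <- sweep(num, 2L, w, `/`)
    num[is.na(num)] <- 0
    diag(A) <- 1 + rowSums(num) / diag(np)
  }
  A <- (A + t(A)) / 2
  relatedness_matrix(A, g$fam[, c("fid", "iid")], np)
}

.grm_files <- function(prefix) {
  list(id = paste0(prefix, ".grm.id"), grm = paste0(prefix, ".grm.gz"))
}

#' Write / read a relatedness matrix in the text GRM dialect
#'
#' Two files: `<prefix>.grm.id` holds one `family id <TAB> individual id`
#' line per animal, and `<prefix>.grm.gz` holds the 1-based lower triangle
#' (diagonal included) as `j <TAB> k <TAB> pair SNP count <TAB> A_jk`, the
#' text convention of GCTA's `--make-grm-gz`. [read_grm()] is the exact
#' inverse.
#'
#' @param a a [relatedness_matrix()].
#' @param prefix file path prefix.
#' @return `write_grm()` invisibly returns `prefix`; `read_grm()` returns a
#'   [relatedness_matrix()].
#' @export
write_grm <- function(a, prefix) {
  stopifnot(inherits(a, "relatedness_matrix"))
  f <- .grm_files(prefix)
  writeLines(paste(a$ids$fid, a$ids$iid, sep = "\t"), f$id)
  n <- nrow(a$A)
  j <- rep.int(seq_len(n), seq_len(n))
  k <- sequence(seq_len(n))
  idx <- cbind(j, k)
  con <- gzfile(f$grm, "wb")
  on.exit(close(con))
  writeLines(paste(j, k, a$n_pairs[idx], sprintf("%.17g", a$A[idx]),
                   sep = "\t"), con)
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  f <- .grm_files(prefix)
  idl <- .split_ws(readLines(f$id))
  if (any(lengths(idl) != 2L)) stop("malformed .grm.id line")
  ids <- data.frame(fid = vapply(idl, `[[`, "", 1L),
                    iid = vapply(idl, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  n <- nrow(ids)
  con <- gzfile(f$grm, "rt")
  on.exit(close(con))
  tri <- read.table(con, sep = "\t", col.names = c("j", "k", "n", "a"),
                    colClasses = c("integer", "integer", "integer",
                                   "numeric"))
  if (nrow(tri) != n * (n + 1L) / 2L)
    stop("truncated GRM triangle: expected ", n * (n + 1L) / 2L,
         " lines, found ", nrow(tri))
  if (any(tri$j < 1L | tri$j > n | tri$k < 1L | tri$k > tri$j))
    stop("GRM triangle index out of range")
  A <- matrix(0, n, n); np <- matrix(0L, n, n)
  A[cbind(tri$j, tri$k)] <- tri$a
  np[cbind(tri$j, tri$k)] <- tri$n
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  np[upper.tri(np)] <- t(np)[upper.tri(np)]
  relatedness_matrix(A, ids, np)
}
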