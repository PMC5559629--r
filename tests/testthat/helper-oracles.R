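# Independent oracles used across the suite. Each one recomputes a result
# by a different route than the package implementation.

# Pure-R Gotoh global aligner with the package's scoring conventions
# (gap run of length L costs open + L*extend; N never matches; tie-breaks
# diagonal > gap-in-second > gap-in-first). Returns score and identity.
r_nw_identity <- function(a, b, match = 2, mismatch = -1, gap_open = -5,
                          gap_extend = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e300
  gi <- gap_open + gap_extend
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b, consumes A
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a, consumes B
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + gap_extend * i
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + gap_extend * j
  sub <- function(x, y) {
    if (x == "N" || y == "N") mismatch else if (x == y) match else mismatch
  }
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        sub(A[i - 1], B[j - 1])
      X[i, j] <- max(M[i - 1, j] + gi, X[i - 1, j] + gap_extend,
                     Y[i - 1, j] + gi)
      Y[i, j] <- max(M[i, j - 1] + gi, Y[i, j - 1] + gap_extend,
                     X[i, j - 1] + gi)
    }
  }
  i <- n + 1; j <- m + 1
  st <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  score <- c(M[i, j], X[i, j], Y[i, j])[st]
  matches <- 0; columns <- 0
  while (i > 1 || j > 1) {
    if (i == 1) { j <- j - 1; columns <- columns + 1; next }
    if (j == 1) { i <- i - 1; columns <- columns + 1; next }
    if (st == 1) {
      columns <- columns + 1
      if (A[i - 1] == B[j - 1] && A[i - 1] != "N") matches <- matches + 1
      st <- which.max(c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
      i <- i - 1; j <- j - 1
    } else if (st == 2) {
      columns <- columns + 1
      st <- which.max(c(M[i - 1, j] + gi, X[i - 1, j] + gap_extend,
                        Y[i - 1, j] + gi))
      i <- i - 1
    } else {
      columns <- columns + 1
      cand <- c(M[i, j - 1] + gi, Y[i, j - 1] + gap_extend,
                X[i, j - 1] + gi)
      st <- c(1, 3, 2)[which.max(cand)]
      j <- j - 1
    }
  }
  list(score = score, identity = 100 * matches / columns)
}

# 201-point grid search over the heritability with the restricted
# likelihood evaluated on the unrotated scale via Cholesky of V(h).
reml_grid_oracle <- function(y, A, npts = 201L) {
  n <- length(y)
  X <- matrix(1, n, 1)
  ll <- function(h) {
    V <- h * A + (1 - h) * diag(n)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(-Inf)
    Vi_y <- backsolve(R, backsolve(R, y, transpose = TRUE))
    Vi_X <- backsolve(R, backsolve(R, X, transpose = TRUE))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(X, Vi_y))
    r <- y - X %*% beta
    Vi_r <- backsolve(R, backsolve(R, r, transpose = TRUE))
    s2 <- sum(r * Vi_r) / (n - 1)
    if (!is.finite(s2) || s2 <= 0) return(-Inf)
    -0.5 * ((n - 1) * (log(2 * pi) + 1 + log(s2)) +
              2 * sum(log(diag(R))) + log(det(XtViX)))
  }
  hs <- seq(0, 1, length.out = npts)
  lls <- vapply(hs, ll, numeric(1))
  list(h2 = hs[which.max(lls)], ll = max(lls))
}

# Spearman r by explicit average-ranking and Pearson on the ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum of all table
# probabilities no larger than the observed one.
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  supp <- max(0, k - n):min(k, m)
  probs <- dhyper(supp, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Element-wise double-loop GRM oracle (pairwise-complete SNP sets).
grm_loop_oracle <- function(calls, p) {
  keep <- p > 0 & p < 1
  x <- calls[, keep, drop = FALSE]
  p <- p[keep]
  n <- nrow(x)
  A <- matrix(0, n, n); np <- matrix(0L, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0; cnt <- 0L
    for (i in seq_along(p)) {
      if (!is.na(x[j, i]) && !is.na(x[k, i])) {
        s <- s + (x[j, i] - 2 * p[i]) * (x[k, i] - 2 * p[i]) /
          (2 * p[i] * (1 - p[i]))
        cnt <- cnt + 1L
      }
    }
    A[j, k] <- s / cnt; np[j, k] <- cnt
  }
  list(A = A, n_pairs = np)
}

# small random genotype_matrix used by several suites
random_genotypes <- function(n = 10L, m = 50L, missing = 0.05, seed = 1L) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * m, replace = TRUE, prob = c(.3, .4, .3)),
                  n, m)
  if (missing > 0) calls[runif(n * m) < missing] <- NA_integer_
  genotype_matrix(
    calls,
    fam = data.frame(fid = "f0", iid = sprintf("an%03d", seq_len(n)),
                     pat = "0", mat = "0", sex = "0", pheno = "-9",
                     stringsAsFactors = FALSE),
    map = data.frame(chr = "1", snp = sprintf("s%04d", seq_len(m)), cm = 0,
                     bp = seq_len(m), stringsAsFactors = FALSE))
}

# random ACGT(N) sequence
random_seq <- function(len, with_n = FALSE) {
  alph <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alph, len, replace = TRUE,
               prob = if (with_n) c(rep(0.24, 4), 0.04) else rep(0.25, 4)),
        collapse = "")
}
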