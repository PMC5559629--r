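#' Eigendecomposition cache for repeated REML fits
#'
#' Decomposes the relationship matrix once, `A = Q L Q'`, so that every
#' subsequent REML fit only rotates the phenotype by `Q'` and evaluates the
#' restricted likelihood against a diagonal covariance in O(animals) per
#' candidate heritability. This is what makes thousands of per-OTU fits and
#' the permutation null affordable.
#'
#' A relationship matrix estimated with pairwise-complete SNP counts is not
#' guaranteed positive semidefinite: a percent of missing calls routinely
#' produces eigenvalues around `-0.01`. Such small dips are repaired by
#' flooring the spectrum at `1e-8 * trace(A)/N`; eigenvalues below
#' `-psd_tol * trace(A)/N` indicate a malformed matrix and raise an error.
#'
#' @param a a [relatedness_matrix()] or a plain symmetric matrix.
#' @param X fixed-effect design matrix; defaults to an intercept column.
#' @param psd_tol relative tolerance for negative eigenvalues (default
#'   0.05, i.e. 5 percent of the mean diagonal).
#' @return An object of class `grm_eigen` with components `Q`, `lambda`,
#'   `X`, `Xr` (rotated design), `ids`.
#' @export
eigen_prepare <- function(a, X = NULL, psd_tol = 0.05) {
  ids <- NULL
  if (inherits(a, "relatedness_matrix")) {
    ids <- a$ids
    a <- a$A
  }
  a <- as.matrix(a)
  n <- nrow(a)
  if (max(abs(a - t(a))) > 1e-8) stop("A must be symmetric")
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X must have one row per animal")
  if (qr(X)$rank < ncol(X)) stop("X must have full column rank")
  e <- eigen(a, symmetric = TRUE)
  scale <- sum(diag(a)) / n
  if (min(e$values) < -psd_tol * scale)
    stop("relationship matrix is not positive semidefinite ",
         "(min eigenvalue ", signif(min(e$values), 4), ")")
  floor_ev <- 1e-8 * scale
  lambda <- pmax(e$values, floor_ev)
  structure(list(Q = e$vectors, lambda = lambda, X = X,
                 Xr = crossprod(e$vectors, X), ids = ids, n = n,
                 p = ncol(X)),
            class = "grm_eigen")
}

# Restricted log-likelihood of the rotated model at heritability h, with the
# total variance profiled out analytically. yr, Xr live in the eigenbasis of
# A; lambda are its (floored) eigenvalues. Returns the log-likelihood up to
# the constant 0.5*log|X'X| which cancels in every comparison we make.
.reml_loglik <- function(h, lambda, Xr, yr) {
  n <- length(yr); p <- ncol(Xr)
  d <- 1 + h * (lambda - 1)
  if (min(d) <= 0) return(list(ll = -Inf, sigma2 = NA_real_))
  w <- 1 / d
  if (p == 1L) {
    x <- Xr[, 1L]
    a11 <- sum(x * x * w)
    b <- sum(x * yr * w)
    r2 <- sum(yr * yr * w) - b * b / a11
    logdetA1 <- log(a11)
  } else {
    sw <- sqrt(w)
    Xw <- Xr * sw
    yw <- yr * sw
    A1 <- crossprod(Xw)
    R <- chol(A1)
    z <- backsolve(R, crossprod(Xw, yw), transpose = TRUE)
    r2 <- sum(yw^2) - sum(z^2)
    logdetA1 <- 2 * sum(log(diag(R)))
  }
  df <- n - p
  sigma2 <- max(r2, 0) / df
  if (sigma2 <= 0) return(list(ll = -Inf, sigma2 = 0))
  ll <- -0.5 * (df * (log(2 * pi) + 1 + log(sigma2)) + sum(log(d)) +
                  logdetA1)
  list(ll = ll, sigma2 = sigma2)
}

# Scalar profile-REML optimizer over h in [0, 1]: coarse grid to bracket,
# then golden-section refinement. Deterministic; no random starts.
.reml_optimize <- function(lambda, Xr, yr, grid_n = 101L, tol = 1e-8) {
  hs <- seq(0, 1, length.out = grid_n)
  lls <- vapply(hs, function(h) .reml_loglik(h, lambda, Xr, yr)$ll,
                numeric(1))
  i <- which.max(lls)
  lo <- hs[max(i - 1L, 1L)]
  hi <- hs[min(i + 1L, grid_n)]
  f <- function(h) .reml_loglik(h, lambda, Xr, yr)$ll
  opt <- optimize(f, lower = lo, upper = hi, maximum = TRUE, tol = tol)
  if (opt$objective >= lls[i]) {
    h <- opt$maximum; ll <- opt$objective
  } else {
    h <- hs[i]; ll <- lls[i]
  }
  # snap to the boundary when it is at least as good
  for (hb in c(0, 1)) {
    llb <- .reml_loglik(hb, lambda, Xr, yr)$ll
    if (llb >= ll) { h <- hb; ll <- llb }
  }
  fit <- .reml_loglik(h, lambda, Xr, yr)
  list(h2 = h, ll = ll, sigma2 = fit$sigma2, ll_null = lls[1L])
}

#' Fit the single-GRM mixed model by REML
#'
#' Maximizes the restricted likelihood of
#' `y ~ Normal(X beta, sigma_u^2 A + sigma_e^2 I)` over the two variance
#' components. The likelihood is profiled to one dimension (the
#' heritability `h2 = sigma_u^2 / (sigma_u^2 + sigma_e^2)`), the total
#' variance is solved analytically, and the scalar problem is optimized on
#' `[0, 1]` after a deterministic grid bracket — boundary solutions at
#' `sigma_u^2 = 0` are returned as such. `loglik_null` is the restricted
#' optimum under `sigma_u^2 = 0`.
#'
#' @param y numeric phenotype vector, no missing values.
#' @param a a [relatedness_matrix()] or a `grm_eigen` cache from
#'   [eigen_prepare()]; must align with `y`.
#' @param X optional fixed-effect design (ignored when `a` is already a
#'   cache); intercept only by default.
#' @return An object of class `variance_components`: `sigma_u2`, `sigma_e2`,
#'   `h2`, `loglik_full`, `loglik_null`, `lr_statistic`, `p_value`,
#'   `converged`, `n_used`.
#' @export
reml_fit <- function(y, a, X = NULL) {
  cache <- if (inherits(a, "grm_eigen")) a else eigen_prepare(a, X = X)
  y <- as.numeric(y)
  n <- cache$n
  if (length(y) != n) stop("length(y) must match the relationship matrix")
  if (anyNA(y)) stop("y must not contain missing values after alignment")
  if (n < 10L) stop("need at least 10 animals for a REML fit")
  if (var(y) == 0) stop("phenotype has zero variance")
  yr <- as.numeric(crossprod(cache$Q, y))
  opt <- .reml_optimize(cache$lambda, cache$Xr, yr)
  .make_vc(opt, n)
}

.make_vc <- function(opt, n) {
  lr <- max(0, 2 * (opt$ll - opt$ll_null))
  structure(list(
    sigma_u2 = opt$h2 * opt$sigma2,
    sigma_e2 = (1 - opt$h2) * opt$sigma2,
    h2 = opt$h2,
    loglik_full = opt$ll,
    loglik_null = opt$ll_null,
    lr_statistic = lr,
    p_value = lrt_pvalue(lr),
    converged = is.finite(opt$ll),
    n_used = n
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "h2 = %.4f (sigma_u2 = %.4g, sigma_e2 = %.4g), LR = %.3f, p = %.4g, n = %d\n",
    x$h2, x$sigma_u2, x$sigma_e2, x$lr_statistic, x$p_value, x$n_used))
  invisible(x)
}

#' Boundary likelihood-ratio p-value
#'
#' The genetic variance sits on the boundary of its parameter space under
#' the null, so the LR statistic is referred to the 50:50 mixture of a point
#' mass at zero and a chi-squared with one degree of freedom:
#' `p = 0.5 * Pr(chisq_1 >= lr)`. Tiny negative statistics are clipped to 0,
#' where the p-value is 0.5.
#'
#' @param lr likelihood-ratio statistic (or a `variance_components` object).
#' @return The mixture p-value.
#' @export
lrt_pvalue <- function(lr) {
  if (inherits(lr, "variance_components")) lr <- lr$lr_statistic
  lr <- pmax(0, lr)
  0.5 * pchisq(lr, df = 1L, lower.tail = FALSE)
}

#' REML fits for many phenotypes sharing one relationship matrix
#'
#' Vectorized version of [reml_fit()]: rotates all phenotype columns at
#' once, evaluates the profile restricted likelihood on the bracketing grid
#' for every column simultaneously, then refines each column with the same
#' golden-section step the scalar fitter uses, so results are identical to
#' independent [reml_fit()] calls. Columns with zero variance are returned
#' as failed rows (`NA` estimates) rather than errors.
#'
#' @param Y numeric matrix, one phenotype per column.
#' @param cache a `grm_eigen` from [eigen_prepare()].
#' @param perm optional permutation of the animals applied to the rows of
#'   the relationship matrix (used by the permutation null); phenotype rows
#'   stay fixed.
#' @return A data frame with one row per column of `Y`: `phenotype`,
#'   `sigma_u2`, `sigma_e2`, `h2`, `loglik_full`, `loglik_null`,
#'   `lr_statistic`, `p_value`, `n_used`, `converged`.
#' @export
reml_fit_batch <- function(Y, cache, perm = NULL) {
  stopifnot(inherits(cache, "grm_eigen"))
  Y <- as.matrix(Y)
  n <- cache$n
  if (nrow(Y) != n) stop("Y must have one row per animal")
  Q <- cache$Q
  if (!is.null(perm)) {
    if (length(perm) != n || anyDuplicated(perm))
      stop("perm must be a permutation of the animals")
    Q <- Q[perm, , drop = FALSE]
  }
  Xr <- crossprod(Q, cache$X)
  lambda <- cache$lambda
  m <- ncol(Y)
  ok <- apply(Y, 2L, function(col) !anyNA(col) && var(col) > 0)
  out <- data.frame(
    phenotype = if (is.null(colnames(Y))) as.character(seq_len(m))
                else colnames(Y),
    sigma_u2 = NA_real_, sigma_e2 = NA_real_, h2 = NA_real_,
    loglik_full = NA_real_, loglik_null = NA_real_,
    lr_statistic = NA_real_, p_value = NA_real_,
    n_used = n, converged = FALSE, stringsAsFactors = FALSE)
  if (!any(ok)) return(out)
  Yr <- crossprod(Q, Y[, ok, drop = FALSE])

  hs <- seq(0, 1, length.out = 101L)
  p <- cache$p
  df <- n - p
  mok <- ncol(Yr)
  llmat <- matrix(-Inf, length(hs), mok)
  if (p == 1L) {
    x <- Xr[, 1L]
    Y2 <- Yr * Yr
    XY <- Yr * x
    for (i in seq_along(hs)) {
      d <- 1 + hs[i] * (lambda - 1)
      if (min(d) <= 0) next
      w <- 1 / d
      a11 <- sum(x * x * w)
      b <- as.numeric(crossprod(XY, w))
      r2 <- pmax(as.numeric(crossprod(Y2, w)) - b * b / a11, 0)
      sigma2 <- r2 / df
      ll <- -0.5 * (df * (log(2 * pi) + 1 + log(sigma2)) + sum(log(d)) +
                      log(a11))
      ll[sigma2 <= 0] <- -Inf
      llmat[i, ] <- ll
    }
  } else {
    for (i in seq_along(hs)) {
      for (j in seq_len(mok))
        llmat[i, j] <- .reml_loglik(hs[i], lambda, Xr, Yr[, j])$ll
    }
  }
  best <- max.col(t(llmat), ties.method = "first")
  res_h <- numeric(mok); res_ll <- numeric(mok); res_s2 <- numeric(mok)
  for (j in seq_len(mok)) {
    i <- best[j]
    yr <- Yr[, j]
    lo <- hs[max(i - 1L, 1L)]; hi <- hs[min(i + 1L, length(hs))]
    f <- function(h) .reml_loglik(h, lambda, Xr, yr)$ll
    opt <- optimize(f, lower = lo, upper = hi, maximum = TRUE, tol = 1e-8)
    h <- opt$maximum; ll <- opt$objective
    if (llmat[i, j] > ll) { h <- hs[i]; ll <- llmat[i, j] }
    for (hb in c(0, 1)) {
      llb <- .reml_loglik(hb, lambda, Xr, yr)$ll
      if (llb >= ll) { h <- hb; ll <- llb }
    }
    res_h[j] <- h; res_ll[j] <- ll
    res_s2[j] <- .reml_loglik(h, lambda, Xr, yr)$sigma2
  }
  ll0 <- llmat[1L, ]
  lr <- pmax(0, 2 * (res_ll - ll0))
  out$sigma_u2[ok] <- res_h * res_s2
  out$sigma_e2[ok] <- (1 - res_h) * res_s2
  out$h2[ok] <- res_h
  out$loglik_full[ok] <- res_ll
  out$loglik_null[ok] <- ll0
  out$lr_statistic[ok] <- lr
  out$p_value[ok] <- lrt_pvalue(lr)
  out$converged[ok] <- is.finite(res_ll)
  out
}
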