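#' Randomly split a sample in half
#'
#' Splits the rows of a response matrix into two disjoint halves whose sizes
#' differ by at most one, reproducibly under a seed. Used for split-sample
#' dimensionality screening (explore on one half, confirm on the other).
#'
#' @param responses respondent-by-item matrix.
#' @param seed integer seed.
#' @return A list with matrices `first` and `second` and the row indices of
#'   the first half in `idx_first`.
#' @export
split_sample <- function(responses, seed = 1L) {
  x <- as.matrix(responses)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows to split")
  set.seed(seed)
  idx <- sort(sample.int(n, ceiling(n / 2)))
  list(first = x[idx, , drop = FALSE], second = x[-idx, , drop = FALSE],
       idx_first = idx)
}

# log-likelihood of a 2x2 table under a bivariate normal with correlation rho
# and thresholds fixed at the margin-implied normal quantiles
tetra_loglik <- function(rho, tab, t1, t2) {
  S <- matrix(c(1, rho, rho, 1), 2L)
  p11 <- mvtnorm::pmvnorm(lower = c(t1, t2), upper = c(Inf, Inf), sigma = S)[1]
  p10 <- stats::pnorm(t1, lower.tail = FALSE) - p11
  p01 <- stats::pnorm(t2, lower.tail = FALSE) - p11
  p00 <- 1 - p11 - p10 - p01
  pr <- pmax(c(p00, p01, p10, p11), 1e-12)
  sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(pr))
}

#' Tetrachoric correlation of two binary items
#'
#' Maximum-likelihood estimate of the correlation of the latent bivariate
#' normal assumed to underlie a pair of dichotomized variables, with the
#' normal thresholds fixed at the quantiles implied by the item margins.
#' Tables with an empty cell push the MLE to the boundary; the estimate is
#' then clamped at +/-0.999 and flagged.
#'
#' @param x,y binary (0/1) vectors of equal length.
#' @return A list with `rho` and logical `clamped`.
#' @export
tetrachoric <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (!all(x %in% 0:1) || !all(y %in% 0:1)) stop("items must be binary 0/1")
  tab <- table(factor(x, 0:1), factor(y, 0:1))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margin: an item has zero variance")
  t1 <- stats::qnorm(1 - mean(x))   # threshold: P(X=1) = P(Z > t1)
  t2 <- stats::qnorm(1 - mean(y))
  clamped <- any(tab == 0)
  if (clamped) {
    # boundary MLE: sign from the association direction
    or_dir <- (tab[2, 2] + 0.5) * (tab[1, 1] + 0.5) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
    return(list(rho = if (or_dir >= 1) 0.999 else -0.999, clamped = TRUE))
  }
  opt <- stats::optimize(tetra_loglik, interval = c(-0.999, 0.999), tab = tab,
                         t1 = t1, t2 = t2, maximum = TRUE, tol = 1e-7)
  rho <- opt$maximum
  if (abs(rho) > 0.999) { rho <- sign(rho) * 0.999; clamped <- TRUE }
  list(rho = rho, clamped = clamped)
}

#' Matrix of pairwise tetrachoric correlations
#'
#' Estimates all pairwise tetrachoric correlations of a binary response
#' matrix and, if the resulting matrix is not positive semidefinite,
#' smooths it by clipping eigenvalues at a small positive floor and
#' rescaling back to unit diagonal (flagged in the result).
#'
#' @param responses binary respondent-by-item matrix (complete cases used).
#' @return An object of class `tetrachoric_matrix`: list with the `rho`
#'   matrix, a logical `clamped` matrix, and flag `smoothed`.
#' @export
tetrachoric_matrix <- function(responses) {
  x <- as.matrix(responses)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  p <- ncol(x)
  R <- diag(p)
  CL <- matrix(FALSE, p, p)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    e <- tetrachoric(x[, i], x[, j])
    R[i, j] <- R[j, i] <- e$rho
    CL[i, j] <- CL[j, i] <- e$clamped
  }
  dimnames(R) <- dimnames(CL) <- list(colnames(x), colnames(x))
  ev <- eigen(R, symmetric = TRUE)
  smoothed <- FALSE
  if (any(ev$values < 0)) {
    smoothed <- TRUE
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
    diag(R) <- 1
    dimnames(R) <- dimnames(CL)
  }
  structure(list(rho = R, clamped = CL, smoothed = smoothed, n = nrow(x)),
            class = "tetrachoric_matrix")
}

#' @export
print.tetrachoric_matrix <- function(x, ...) {
  cat(sprintf("Tetrachoric correlation matrix (%d items, n = %d%s%s)\n",
              ncol(x$rho), x$n,
              if (any(x$clamped)) ", boundary pairs clamped" else "",
              if (x$smoothed) ", PSD-smoothed" else ""))
  print(round(x$rho, 3))
  invisible(x)
}

as_corr <- function(corr) {
  if (inherits(corr, "tetrachoric_matrix")) corr$rho else as.matrix(corr)
}

#' Eigenvalues for a scree inspection
#'
#' Descending eigenvalues of a correlation matrix; their sum equals the
#' number of items. A single eigenvalue above 1 with the rest below is the
#' classic scree signature of a unidimensional measure.
#'
#' @param corr a correlation matrix or [tetrachoric_matrix].
#' @return Numeric vector of descending eigenvalues.
#' @export
scree_eigenvalues <- function(corr) {
  R <- as_corr(corr)
  sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Single-factor solution by unweighted least squares
#'
#' Fits the one-factor model \eqn{R \approx \lambda\lambda^\top +
#' \mathrm{diag}(1 - \lambda^2)} by minimizing the sum of squared
#' off-diagonal residuals. The sign of the solution is canonicalized to a
#' positive mean loading. A Heywood loading (|loading| > 1) is clamped and
#' flagged. SRMR is the root mean square of the off-diagonal residuals.
#'
#' @param corr a correlation matrix or [tetrachoric_matrix].
#' @return An object of class `factor_solution`: `loadings`, descending
#'   `eigenvalues`, `srmr`, `heywood` flag.
#' @export
fit_single_factor <- function(corr) {
  R <- as_corr(corr)
  p <- ncol(R)
  ev <- eigen(R, symmetric = TRUE)
  lam <- ev$vectors[, 1L] * sqrt(max(ev$values[1L], 0))  # PCA start
  obj <- function(l) {
    E <- R - tcrossprod(l); diag(E) <- 0
    sum(E^2)
  }
  grad <- function(l) {
    E <- R - tcrossprod(l); diag(E) <- 0
    -4 * drop(E %*% l)
  }
  opt <- stats::optim(lam, obj, grad, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-14))
  lam <- opt$par
  # a matrix with no common structure makes the loading vector indeterminate
  # (any single-spike vector fits the off-diagonal equally well); prefer the
  # null solution when it is as good as the fitted one
  if (obj(rep(0, p)) <= opt$value + 1e-12) lam <- rep(0, p)
  if (mean(lam) < 0) lam <- -lam
  heywood <- any(abs(lam) > 1)
  lam <- pmin(pmax(lam, -1), 1)
  E <- R - tcrossprod(lam); diag(E) <- 0
  srmr <- sqrt(sum(E[upper.tri(E)]^2) / sum(upper.tri(E)))
  structure(list(loadings = lam, eigenvalues = scree_eigenvalues(R),
                 srmr = srmr, heywood = heywood),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat("Single-factor solution (unweighted least squares)\n")
  cat("  loadings:", paste(sprintf("%.2f", x$loadings), collapse = " "), "\n")
  cat(sprintf("  first eigenvalue %.2f, SRMR %.3f%s\n", x$eigenvalues[1L],
              x$srmr, if (x$heywood) " [Heywood case, clamped]" else ""))
  invisible(x)
}

#' Split-sample dimensionality screen
#'
#' Convenience wrapper: splits the sample, computes the tetrachoric matrix
#' and scree eigenvalues on the first half and the single-factor solution
#' on the second half. This is a deliberately simplified screen -- scree on
#' tetrachoric correlations plus an unweighted least squares single factor
#' with SRMR -- standing in for a full categorical-data EFA/CFA; its purpose
#' is the binary decision the rest of the pipeline needs (is one factor
#' enough to support a unidimensional IRT model?).
#'
#' @param responses binary response matrix.
#' @param seed split seed.
#' @return List with `eigenvalues` (exploration half), `solution`
#'   (confirmation half [fit_single_factor]), `n_explore`, `n_confirm`,
#'   and `one_factor` (TRUE when exactly one exploration eigenvalue
#'   exceeds 1).
#' @export
dimensionality_screen <- function(responses, seed = 1L) {
  halves <- split_sample(responses, seed = seed)
  Re <- tetrachoric_matrix(halves$first)
  eigs <- scree_eigenvalues(Re)
  Rc <- tetrachoric_matrix(halves$second)
  sol <- fit_single_factor(Rc)
  list(eigenvalues = eigs, solution = sol,
       n_explore = nrow(halves$first), n_confirm = nrow(halves$second),
       one_factor = sum(eigs > 1) == 1L,
       method = "tetrachoric + scree + ULS single factor (simplified screen)")
}
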