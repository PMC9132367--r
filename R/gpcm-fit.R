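#' Fit a generalized partial credit model by marginal maximum likelihood
#'
#' Calibrates GPCM item parameters from a respondent-by-item matrix of
#' categorical responses by an EM algorithm. The latent trait is integrated
#' out against a standard-normal prior on a quadrature grid (the E step);
#' each item's discrimination and thresholds are then updated by maximizing
#' its expected complete-data log-likelihood (the M step, a smooth concave
#' problem solved by BFGS from the current estimates, which guarantees the
#' marginal log-likelihood never decreases). The prior fixes the latent
#' scale (mean 0, SD 1); no item-side constraint is imposed.
#'
#' Responses are coded `0, 1, ..., K_j - 1`. Rows must be complete: the
#' analytic data set is complete-case and the caller decides how to handle
#' missingness (see [read_responses]). An item observed in fewer than two
#' categories cannot be calibrated and raises an error naming the item.
#'
#' @param responses integer matrix or data frame, respondents by items.
#' @param grid a [trait_grid] for the prior quadrature (default 61-point
#'   Gauss--Hermite).
#' @param tol convergence tolerance on the maximum absolute parameter change
#'   between EM iterations.
#' @param max_iter maximum number of EM iterations; non-convergence is
#'   flagged on the returned object and warned about, never silent.
#' @param verbose print the marginal log-likelihood each iteration.
#' @return An object of class `gpcm`: a list with the calibrated `bank`
#'   (an [item_bank]), `logLik`, the per-iteration `ll_trace`, `iter`,
#'   `converged`, the quadrature `grid`, sample size `n` and the response
#'   matrix used.
#' @examples
#' set.seed(1)
#' bank <- item_bank(a = runif(6, 0.8, 2), b = runif(6, -1.5, 1.5))
#' x <- simulate_responses(bank, theta = rnorm(500))
#' fit <- gpcm(x)
#' coef(fit)
#' @seealso [predict.gpcm] for EAP scoring, [test_information] for the TIF.
#' @export
gpcm <- function(responses, grid = trait_grid(), tol = 1e-4,
                 max_iter = 500L, verbose = FALSE) {
  x <- as.matrix(responses)
  if (!is.numeric(x)) storage.mode(x) <- "numeric"
  if (anyNA(x))
    stop("responses contain missing values; supply complete cases")
  if (!all(x == round(x)) || any(x < 0))
    stop("responses must be nonnegative integer category codes")
  if (!is_trait_grid(grid)) stop("'grid' is not a valid trait_grid")
  n <- nrow(x); p <- ncol(x)
  if (n < 2L || p < 1L) stop("need at least 2 respondents and 1 item")
  items <- colnames(x)
  if (is.null(items)) items <- sprintf("item%02d", seq_len(p))

  K <- integer(p)
  for (j in seq_len(p)) {
    obs <- sort(unique(x[, j]))
    if (length(obs) < 2L)
      stop(sprintf("item '%s' has zero response variance and cannot be calibrated",
                   items[j]))
    K[j] <- max(obs) + 1L
  }

  # collapse to unique response patterns: the likelihood depends on the data
  # only through pattern counts
  key <- apply(x, 1L, paste, collapse = ",")
  tab <- table(key)
  cnt <- as.numeric(tab)
  pat <- x[match(names(tab), key), , drop = FALSE]
  m <- nrow(pat)

  nodes <- grid$nodes; wts <- grid$weights; Q <- length(nodes)
  # start discriminations at 1 and thresholds at the adjacent-category
  # logits of the observed proportions (the PCM solution at theta = 0);
  # keeps early M-steps away from the flat a -> 0 ridge
  a <- rep(1, p)
  b <- lapply(seq_len(p), function(j) {
    pk <- tabulate(x[, j] + 1L, nbins = K[j]) / n
    pk <- pmax(pk, 1 / (2 * n))
    pmin(pmax(log(pk[-K[j]] / pk[-1L]), -3), 3)
  })

  item_nll <- function(par, Nk, nodes, Kj) {
    aa <- exp(par[1L]); bb <- par[-1L]
    P <- gpcm_prob(nodes, aa, bb)            # Q x K
    -sum(Nk * t(log(pmax(P, 1e-300))))
  }
  item_ngr <- function(par, Nk, nodes, Kj) {
    aa <- exp(par[1L]); bb <- par[-1L]
    P <- gpcm_prob(nodes, aa, bb)            # Q x K
    kk <- 0:(Kj - 1L)
    Bcum <- c(0, cumsum(bb))
    U <- outer(nodes, kk) - matrix(Bcum, Q, Kj, byrow = TRUE)  # k*theta - Bcum_k
    Eq <- rowSums(P * U)
    g_a <- sum(t(Nk) * (U - Eq))
    Ncol <- colSums(Nk)                       # expected n at each node
    g_b <- numeric(Kj - 1L)
    for (v in seq_len(Kj - 1L)) {
      Sv <- rowSums(P[, (v + 1L):Kj, drop = FALSE])   # P(X >= v | theta_q)
      Mv <- colSums(Nk[(v + 1L):Kj, , drop = FALSE])  # expected count X >= v
      g_b[v] <- aa * sum(Ncol * Sv - Mv)
    }
    -c(aa * g_a, g_b)
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E step: pattern x node log-likelihood
    LL <- matrix(0, m, Q)
    Plist <- vector("list", p)
    for (j in seq_len(p)) {
      Pj <- gpcm_prob(nodes, a[j], b[[j]])    # Q x K_j
      Plist[[j]] <- Pj
      LL <- LL + t(log(pmax(Pj, 1e-300)))[pat[, j] + 1L, , drop = FALSE]
    }
    LW <- sweep(LL, 2L, log(wts), `+`)
    mx <- apply(LW, 1L, max)
    A <- exp(LW - mx)
    rs <- rowSums(A)
    ll <- sum(cnt * (mx + log(rs)))
    ll_trace <- c(ll_trace, ll)
    if (verbose) cat(sprintf("iter %3d  logLik %.6f\n", iter, ll))
    post <- (A / rs) * cnt                    # count-weighted posterior

    # M step, one smooth optimization per item
    delta <- 0
    for (j in seq_len(p)) {
      Nk <- rowsum(post, group = pat[, j], reorder = TRUE)  # K_j x Q
      full <- matrix(0, K[j], Q)
      full[as.integer(rownames(Nk)) + 1L, ] <- Nk
      par0 <- c(log(a[j]), b[[j]])
      # box constraints keep the search off the unidentified a -> 0,
      # |b| -> Inf ridge where the likelihood is flat
      opt <- stats::optim(par0, item_nll, item_ngr, Nk = full, nodes = nodes,
                          Kj = K[j], method = "L-BFGS-B",
                          lower = c(log(1e-2), rep(-15, K[j] - 1L)),
                          upper = c(log(50), rep(15, K[j] - 1L)),
                          control = list(maxit = 200L, factr = 1e4))
      anew <- exp(opt$par[1L]); bnew <- opt$par[-1L]
      delta <- max(delta, abs(anew - a[j]), abs(bnew - b[[j]]))
      a[j] <- anew; b[[j]] <- bnew
    }
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d iterations (last max change %.2e)",
                    iter, delta))

  structure(list(bank = item_bank(a, b, items = items),
                 logLik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
                 iter = iter, converged = converged, grid = grid,
                 n = n, n_patterns = m, responses = x,
                 call = match.call()),
            class = "gpcm")
}

#' @export
print.gpcm <- function(x, ...) {
  cat("Generalized partial credit model (marginal maximum likelihood)\n")
  cat(sprintf("  %d respondents, %d items, %d response patterns\n",
              x$n, length(x$bank$a), x$n_patterns))
  cat(sprintf("  logLik %.2f after %d EM iterations (%s)\n", x$logLik, x$iter,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.gpcm <- function(object, ...) {
  cf <- coef(object)
  pbar <- colMeans(object$responses)
  info1 <- vapply(seq_along(object$bank$a), function(j)
    item_information(0, object$bank$a[j], object$bank$b[[j]]), 0)
  out <- list(coefficients = cbind(cf, mean_score = pbar, info_at_0 = info1),
              logLik = object$logLik, n = object$n, iter = object$iter,
              converged = object$converged,
              AIC = -2 * object$logLik + 2 * sum(object$bank$K),
              BIC = -2 * object$logLik + log(object$n) * sum(object$bank$K))
  class(out) <- "summary.gpcm"
  out
}

#' @export
print.summary.gpcm <- function(x, ...) {
  cat("GPCM calibration\n")
  print(round(x$coefficients, 3))
  cat(sprintf("\nlogLik %.2f  AIC %.1f  BIC %.1f  (n = %d, %d EM iterations%s)\n",
              x$logLik, x$AIC, x$BIC, x$n, x$iter,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' @export
coef.gpcm <- function(object, ...) coef(object$bank)

#' @export
logLik.gpcm <- function(object, ...) {
  structure(object$logLik, df = sum(object$bank$K), nobs = object$n,
            class = "logLik")
}

#' Score respondents under a fitted GPCM
#'
#' Computes either expected a posteriori (EAP) factor scores -- the
#' posterior mean of the latent trait given the responses on the chosen
#' item subset, under the model's standard-normal prior -- or plain summed
#' scores over the subset.
#'
#' @param object a fitted [gpcm] model.
#' @param newdata response matrix; defaults to the calibration data.
#' @param subset item indices of the form to score (default all items).
#' @param type `"eap"` for factor scores or `"sum"` for summed scores.
#' @param ... unused.
#' @return Numeric vector of scores, one per respondent.
#' @export
predict.gpcm <- function(object, newdata = NULL, subset = NULL,
                         type = c("eap", "sum"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$responses
  if (type == "eap") eap_scores(object$bank, newdata, subset, grid = object$grid)
  else summed_scores(newdata, subset)
}

#' @export
residuals.gpcm <- function(object, ...) {
  # raw item residuals: observed response minus model-expected score at the
  # respondent's EAP estimate
  th <- predict(object, type = "eap")
  res <- object$responses
  for (j in seq_along(object$bank$a)) {
    P <- gpcm_prob(th, object$bank$a[j], object$bank$b[[j]])
    res[, j] <- object$responses[, j] - drop(P %*% (0:(ncol(P) - 1L)))
  }
  res
}

#' Plot the test information function of a fitted GPCM
#'
#' Draws the TIF over a trait range, with the standard error of measurement
#' \eqn{1/\sqrt{\mathrm{TIF}}} on a secondary curve, and optionally the TIF
#' of a short form for comparison.
#'
#' @param x a fitted [gpcm] model or an [item_bank].
#' @param subset optional item indices of a short form to overlay.
#' @param theta_range trait range to draw.
#' @param ... passed to [graphics::plot].
#' @export
plot.gpcm <- function(x, subset = NULL, theta_range = c(-5, 4), ...) {
  th <- seq(theta_range[1], theta_range[2], length.out = 201L)
  tif <- test_information(x, th)
  graphics::plot(th, tif, type = "l", lwd = 2, xlab = expression(theta),
                 ylab = "Test information", ...)
  if (!is.null(subset)) {
    graphics::lines(th, test_information(x, th, subset), lwd = 2, lty = 2)
    graphics::legend("topright", c("full form", "short form"),
                     lty = c(1, 2), lwd = 2, bty = "n")
  }
  invisible(x)
}

#' Simulate response matrices from a fitted GPCM
#'
#' @param object a fitted [gpcm] model.
#' @param nsim number of data sets.
#' @param seed optional integer seed.
#' @param theta latent traits to simulate at; defaults to fresh
#'   standard-normal draws of the calibration sample size.
#' @param ... unused.
#' @return A list of `nsim` response matrices (a single matrix if
#'   `nsim = 1`).
#' @export
simulate.gpcm <- function(object, nsim = 1, seed = NULL, theta = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    th <- if (is.null(theta)) stats::rnorm(object$n) else theta
    out[[i]] <- simulate_responses(object$bank, th)
  }
  if (nsim == 1L) out[[1L]] else out
}
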