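#' GPCM category response probabilities
#'
#' Category probabilities of the generalized partial credit model. For an
#' item with categories \eqn{k = 0, \dots, K-1}, discrimination \eqn{a} and
#' thresholds \eqn{b_1, \dots, b_{K-1}},
#' \deqn{P(X = k \mid \theta) \propto \exp\{\sum_{v \le k} a(\theta - b_v)\},}
#' with the empty sum for \eqn{k = 0}. Binary items reduce to the
#' two-parameter logistic: \eqn{P(X = 1) = \mathrm{logit}^{-1}\{a(\theta - b)\}}.
#'
#' @param theta numeric vector of latent-trait values (finite).
#' @param a positive discrimination.
#' @param b numeric vector of thresholds.
#' @return A `length(theta)` by `K` matrix of probabilities; rows sum to 1.
#' @examples
#' gpcm_prob(0, a = 1, b = 0)          # c(0.5, 0.5)
#' gpcm_prob(1, a = 1.2, b = -1)[, 2]  # plogis(2.4)
#' @export
gpcm_prob <- function(theta, a, b) {
  if (any(!is.finite(theta))) stop("'theta' must be finite")
  if (!is.finite(a) || a < 0) stop("'a' must be finite and nonnegative")
  K <- length(b) + 1L
  # cumulative logits s_k = a * (k*theta - sum(b[1..k])), s_0 = 0
  Bcum <- c(0, cumsum(b))
  s <- a * (outer(theta, 0:(K - 1L)) - matrix(Bcum, length(theta), K, byrow = TRUE))
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}

#' Item and test information
#'
#' Fisher information of a GPCM item at trait values `theta`:
#' \eqn{I_j(\theta) = a_j^2 \,\mathrm{Var}(X_j \mid \theta)}, which for a
#' binary item is \eqn{a^2 P(1-P)}. The test information function (TIF) of
#' a form is the pointwise sum over its items, and the standard error of
#' measurement is \eqn{1/\sqrt{\mathrm{TIF}}}.
#'
#' @param theta numeric vector of trait values.
#' @param a,b item parameters as in [gpcm_prob].
#' @return `item_information`: numeric vector of nonnegative information
#'   values. `test_information`: same, summed over the items in `subset`.
#' @examples
#' item_information(0, a = 2, b = 0)  # a^2/4 = 1
#' @export
item_information <- function(theta, a, b) {
  P <- gpcm_prob(theta, a, b)
  k <- 0:(ncol(P) - 1L)
  m1 <- drop(P %*% k)
  m2 <- drop(P %*% k^2)
  a^2 * (m2 - m1^2)
}

#' @param bank an `item_bank` (or fitted [gpcm] model).
#' @param subset integer indices of the items forming the form.
#' @rdname item_information
#' @export
test_information <- function(bank, theta, subset = NULL) {
  bank <- as_item_bank(bank)
  if (is.null(subset)) subset <- seq_along(bank$a)
  subset <- check_subset(subset, length(bank$a))
  out <- numeric(length(theta))
  for (j in subset) out <- out + item_information(theta, bank$a[j], bank$b[[j]])
  out
}

#' Matrix of item information values at a set of trait points
#'
#' @inheritParams test_information
#' @param theta numeric vector of trait values (e.g. assembly anchors).
#' @return items x theta matrix of information values.
#' @keywords internal
information_matrix <- function(bank, theta) {
  bank <- as_item_bank(bank)
  t(vapply(seq_along(bank$a),
           function(j) item_information(theta, bank$a[j], bank$b[[j]]),
           numeric(length(theta))))
}
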