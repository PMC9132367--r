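#' Summed and EAP scores for an item subset
#'
#' `summed_scores` adds the item scores over the items of a form;
#' `eap_scores` computes expected a posteriori factor scores, the posterior
#' mean of the latent trait given the form's responses under a
#' standard-normal prior:
#' \deqn{\hat\theta_i = \frac{\sum_q \theta_q L_i(\theta_q) w_q}
#'                          {\sum_q L_i(\theta_q) w_q}.}
#' Both operate on complete cases: a missing response within the subset is
#' an error, mirroring the complete-case analytic contract.
#'
#' @param responses respondent-by-item matrix of category codes.
#' @param subset item indices of the form (default all columns).
#' @param bank an [item_bank] or fitted [gpcm] model.
#' @param grid a [trait_grid] for the posterior quadrature.
#' @return Numeric vector of scores, one per respondent.
#' @examples
#' summed_scores(rbind(c(1, 0, 1)))  # 2
#' @export
summed_scores <- function(responses, subset = NULL) {
  x <- as.matrix(responses)
  if (is.null(subset)) subset <- seq_len(ncol(x))
  subset <- check_subset(subset, ncol(x))
  x <- x[, subset, drop = FALSE]
  if (anyNA(x))
    stop("missing responses within the scored subset; complete cases required")
  as.numeric(rowSums(x))
}

#' @rdname summed_scores
#' @export
eap_scores <- function(bank, responses, subset = NULL, grid = trait_grid()) {
  bank <- as_item_bank(bank)
  x <- as.matrix(responses)
  if (ncol(x) != length(bank$a))
    stop("response matrix width must match the item bank")
  if (is.null(subset)) subset <- seq_along(bank$a)
  subset <- check_subset(subset, length(bank$a))
  if (!is_trait_grid(grid)) stop("'grid' is not a valid trait_grid")
  xs <- x[, subset, drop = FALSE]
  if (anyNA(xs))
    stop("missing responses within the scored subset; complete cases required")

  nodes <- grid$nodes; wts <- grid$weights; Q <- length(nodes)
  # work on unique patterns of the subset
  key <- apply(xs, 1L, paste, collapse = ",")
  u <- !duplicated(key)
  pat <- xs[u, , drop = FALSE]
  LL <- matrix(0, nrow(pat), Q)
  for (idx in seq_along(subset)) {
    j <- subset[idx]
    Pj <- gpcm_prob(nodes, bank$a[j], bank$b[[j]])
    LL <- LL + t(log(pmax(Pj, 1e-300)))[pat[, idx] + 1L, , drop = FALSE]
  }
  LW <- sweep(LL, 2L, log(wts), `+`)
  mx <- apply(LW, 1L, max)
  A <- exp(LW - mx)
  eap_u <- drop(A %*% nodes) / rowSums(A)
  eap_u[match(key, key[u])]
}
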