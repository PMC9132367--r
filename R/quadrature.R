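#' Quadrature grid for the latent trait
#'
#' Builds a quadrature representation of the standard-normal latent-trait
#' prior used throughout marginal maximum likelihood estimation and EAP
#' scoring. The default is an equally spaced grid on `range` with weights
#' proportional to the normal density -- for smooth integrands that decay
#' to zero well inside the interval this trapezoid-type rule is
#' exponentially accurate, and it keeps every node inside the plausible
#' trait range. A genuine Gauss--Hermite rule (Golub--Welsch nodes and
#' weights) is available as an alternative; its extreme-node weights
#' underflow for large `n` and are floored at a tiny positive value before
#' renormalization.
#'
#' @param n number of quadrature nodes (default 61).
#' @param type `"even"` (default) for an equally spaced grid on `range`
#'   weighted by the normal density, or `"hermite"` for Gauss--Hermite.
#' @param range numeric length-2 interval for `type = "even"`; ignored for
#'   the Hermite rule.
#' @return An object of class `trait_grid`: a list with strictly increasing
#'   `nodes` and positive `weights` summing to one.
#' @examples
#' g <- trait_grid(21)
#' sum(g$weights * g$nodes^2)  # ~ 1, the prior variance
#' @export
trait_grid <- function(n = 61L, type = c("even", "hermite"), range = c(-6, 6)) {
  type <- match.arg(type)
  n <- as.integer(n)
  if (n < 3L) stop("need at least 3 quadrature nodes")
  if (type == "hermite") {
    # Golub-Welsch: physicists' Hermite recurrence has off-diagonals sqrt(i/2);
    # eigenvalues are the nodes, squared first eigenvector components the
    # normalized weights. theta = sqrt(2) * x maps to the N(0,1) prior.
    off <- sqrt(seq_len(n - 1L) / 2)
    J <- matrix(0, n, n)
    J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
    J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    nodes <- sqrt(2) * e$values[ord]
    weights <- pmax(e$vectors[1L, ord]^2, 1e-300)
    weights <- weights / sum(weights)
  } else {
    if (length(range) != 2L || range[1] >= range[2])
      stop("'range' must be an increasing length-2 interval")
    nodes <- seq(range[1], range[2], length.out = n)
    weights <- stats::dnorm(nodes)
    weights <- weights / sum(weights)
  }
  structure(list(nodes = nodes, weights = weights, type = type),
            class = "trait_grid")
}

#' @export
print.trait_grid <- function(x, ...) {
  cat(sprintf("Latent-trait quadrature grid: %d %s nodes on [%.2f, %.2f]\n",
              length(x$nodes), x$type, min(x$nodes), max(x$nodes)))
  invisible(x)
}

is_trait_grid <- function(x) {
  inherits(x, "trait_grid") &&
    all(diff(x$nodes) > 0) &&
    all(x$weights > 0) &&
    abs(sum(x$weights) - 1) < 1e-10
}
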