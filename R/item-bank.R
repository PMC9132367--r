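#' Item parameter banks
#'
#' An `item_bank` holds generalized partial credit model (GPCM) parameters
#' for a set of items: a positive discrimination `a[j]` per item and a
#' vector of thresholds `b[[j]]` (length `K_j - 1` for an item with `K_j`
#' response categories; binary items have exactly one threshold).
#'
#' @param a numeric vector of nonnegative discriminations (calibration
#'   always yields positive values; zero is allowed for constructed banks,
#'   giving a flat item).
#' @param b list of numeric threshold vectors, one per item; a plain numeric
#'   vector is accepted for all-binary banks.
#' @param items optional character vector of item names.
#' @return An object of class `item_bank`.
#' @examples
#' bank <- item_bank(a = c(1, 1.5), b = c(-1, 0.5))
#' bank
#' @export
item_bank <- function(a, b, items = NULL) {
  if (is.numeric(b)) b <- as.list(b)
  if (length(a) != length(b))
    stop("'a' and 'b' must describe the same number of items")
  if (any(!is.finite(a)) || any(a < 0))
    stop("discriminations must be finite and nonnegative")
  for (bj in b) {
    if (!is.numeric(bj) || length(bj) < 1L || any(!is.finite(bj)))
      stop("each item needs at least one finite threshold")
  }
  if (is.null(items)) items <- sprintf("item%02d", seq_along(a))
  structure(list(a = as.numeric(a), b = lapply(b, as.numeric),
                 K = vapply(b, length, 1L) + 1L, items = items),
            class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("GPCM item bank: %d items (%s)\n", length(x$a),
              if (all(x$K == 2L)) "all binary"
              else sprintf("%d-%d categories", min(x$K), max(x$K))))
  print(coef(x), digits = 3)
  invisible(x)
}

#' @export
coef.item_bank <- function(object, ...) {
  kmax <- max(object$K) - 1L
  out <- matrix(NA_real_, length(object$a), 1L + kmax,
                dimnames = list(object$items,
                                c("a", paste0("b", seq_len(kmax)))))
  out[, 1L] <- object$a
  for (j in seq_along(object$b)) out[j, 1L + seq_along(object$b[[j]])] <- object$b[[j]]
  out
}

#' @export
length.item_bank <- function(x) length(x$a)

#' Coerce to an item bank
#'
#' @param x an `item_bank`, a fitted [gpcm] model, or a list with elements
#'   `a` and `b`.
#' @return An `item_bank`.
#' @export
as_item_bank <- function(x) {
  if (inherits(x, "item_bank")) return(x)
  if (inherits(x, "gpcm")) return(x$bank)
  if (is.list(x) && !is.null(x$a) && !is.null(x$b))
    return(item_bank(x$a, x$b, items = x$items))
  stop("cannot interpret 'x' as an item bank")
}

check_subset <- function(subset, p) {
  if (length(subset) == 0L) stop("item subset must be non-empty")
  subset <- as.integer(subset)
  if (anyDuplicated(subset) || any(subset < 1L) || any(subset > p))
    stop("item subset indices must be unique and within the bank")
  subset
}
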