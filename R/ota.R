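#' Anchor points for test assembly
#'
#' The assembly objective evaluates the test information function at a small
#' set of anchor points spanning the latent trait. The default anchors are
#' (-5, -3, -1, 1, 3) with equal weights.
#'
#' @param anchors strictly increasing numeric vector of trait values.
#' @param weights positive per-anchor weights (default equal).
#' @return An object of class `anchor_set`.
#' @export
anchor_set <- function(anchors = c(-5, -3, -1, 1, 3),
                       weights = rep(1, length(anchors))) {
  if (any(diff(anchors) <= 0)) stop("anchors must be strictly increasing")
  if (length(weights) != length(anchors) || any(weights <= 0))
    stop("weights must be positive, one per anchor")
  structure(list(anchors = anchors, weights = weights), class = "anchor_set")
}

new_short_form <- function(subset, length, objective, formulation, tif = NULL) {
  structure(list(items = sort(as.integer(subset)), length = as.integer(length),
                 objective = objective, formulation = formulation, tif = tif),
            class = "short_form")
}

#' @export
print.short_form <- function(x, ...) {
  cat(sprintf("Short form, %d items {%s}: %s objective %.4f\n", x$length,
              paste(x$items, collapse = ", "), x$formulation, x$objective))
  invisible(x)
}

form_objective <- function(I, subset, weights, formulation) {
  tifa <- colSums(I[subset, , drop = FALSE])
  if (formulation == "sum") sum(weights * tifa) else min(tifa)
}

#' Exhaustively enumerate the optimal short form
#'
#' Evaluates every item subset of the requested length and returns the one
#' maximizing the assembly objective: either the anchor-weighted sum of the
#' short form's test information at the anchors (`"sum"`) or its minimum
#' over the anchors (`"maximin"`). Ties are broken toward the
#' lexicographically smallest index set. This is the independent oracle for
#' [assemble_short_form] and is feasible for banks of modest size.
#'
#' @param bank an [item_bank] or fitted [gpcm] model.
#' @param length form length, between 3 and one less than the bank size.
#' @param anchors an [anchor_set].
#' @param formulation `"sum"` (default) or `"maximin"`.
#' @return A `short_form`.
#' @export
enumerate_optimal <- function(bank, length, anchors = anchor_set(),
                              formulation = c("sum", "maximin")) {
  formulation <- match.arg(formulation)
  bank <- as_item_bank(bank)
  p <- base::length(bank$a)
  if (length < 3L || length > p - 1L)
    stop("form length must be between 3 and one less than the bank size")
  if (choose(p, length) > 1e6)
    stop("enumeration over more than 1e6 subsets refused; use assemble_short_form")
  I <- information_matrix(bank, anchors$anchors)
  best <- -Inf; best_set <- NULL
  # combn walks subsets in lexicographic order; strict improvement keeps the
  # lexicographically smallest among ties
  utils::combn(p, length, FUN = function(s) {
    v <- form_objective(I, s, anchors$weights, formulation)
    if (v > best) { best <<- v; best_set <<- s }
    0L
  })
  new_short_form(best_set, length, best, formulation)
}

#' Assemble a short form by branch and bound
#'
#' Solves the same binary program as [enumerate_optimal] -- one inclusion
#' variable per item, a cardinality constraint fixing the form length, and
#' either the anchor-weighted-sum or the maximin test-information objective
#' -- by depth-first branch and bound with an admissible upper bound
#' (the best completion using the largest remaining per-anchor
#' contributions). Exploring inclusion before exclusion in index order,
#' with strict-improvement updates, reproduces the lexicographically
#' smallest optimal subset, so the result is guaranteed to match the
#' enumeration oracle.
#'
#' @inheritParams enumerate_optimal
#' @return A `short_form`.
#' @examples
#' bank <- item_bank(a = c(2, 2, 2, rep(0.3, 5)), b = rep(-1, 8))
#' assemble_short_form(bank, 3)$items  # the three discriminating items
#' @export
assemble_short_form <- function(bank, length, anchors = anchor_set(),
                                formulation = c("sum", "maximin")) {
  formulation <- match.arg(formulation)
  bank <- as_item_bank(bank)
  p <- base::length(bank$a)
  L <- as.integer(length)
  if (L < 3L || L > p - 1L)
    stop("form length must be between 3 and one less than the bank size")
  I <- information_matrix(bank, anchors$anchors)   # p x A
  w <- anchors$weights
  A <- ncol(I)

  if (formulation == "sum") {
    contrib <- drop(I %*% w)                       # separable objective
    # suffix maxima: best completion picking the top remaining contributions
    suffix_sorted <- lapply(seq_len(p + 1L), function(j)
      if (j > p) numeric(0) else sort(contrib[j:p], decreasing = TRUE))
  }
  # per-anchor suffix cumulative maxima for the maximin bound
  suffix_top <- function(j, need) {
    if (need == 0L) return(numeric(A))
    rows <- seq(j, p)
    apply(I[rows, , drop = FALSE], 2L, function(col)
      sum(sort(col, decreasing = TRUE)[seq_len(min(need, base::length(col)))]))
  }

  best <- -Inf; best_set <- integer(0)
  sel <- integer(L)

  recurse <- function(j, m, acc) {
    # j: next item index considered; m: items chosen; acc: per-anchor TIF
    if (m == L) {
      v <- if (formulation == "sum") sum(w * acc) else min(acc)
      if (v > best) { best <<- v; best_set <<- sel[seq_len(L)] }
      return(invisible())
    }
    if (j > p || p - j + 1L < L - m) return(invisible())
    # admissible bound on the best completion
    ub <- if (formulation == "sum") {
      sum(w * acc) + sum(suffix_sorted[[j]][seq_len(L - m)])
    } else {
      min(acc + suffix_top(j, L - m))
    }
    if (ub <= best) return(invisible())
    sel[m + 1L] <<- j
    recurse(j + 1L, m + 1L, acc + I[j, ])          # include j first
    recurse(j + 1L, m, acc)                        # then exclude
    invisible()
  }
  recurse(1L, 0L, numeric(A))
  new_short_form(best_set, L, best, formulation)
}

#' Ladder of candidate short forms
#'
#' Assembles one optimal short form per candidate length (3 up to one item
#' fewer than the full form) and stores each form's TIF on a reporting
#' grid. Forms of different lengths need not be nested.
#'
#' @inheritParams enumerate_optimal
#' @param theta_grid trait values at which each candidate's TIF is stored.
#' @return An object of class `form_ladder`: a list of `short_form`s named
#'   by length, with attributes `anchors` and `theta_grid`.
#' @export
candidate_ladder <- function(bank, anchors = anchor_set(),
                             formulation = c("sum", "maximin"),
                             theta_grid = seq(-6, 6, by = 0.25)) {
  formulation <- match.arg(formulation)
  bank <- as_item_bank(bank)
  p <- base::length(bank$a)
  lengths <- 3:(p - 1L)
  forms <- lapply(lengths, function(L) {
    f <- assemble_short_form(bank, L, anchors, formulation)
    f$tif <- test_information(bank, theta_grid, f$items)
    f
  })
  names(forms) <- as.character(lengths)
  structure(forms, anchors = anchors, theta_grid = theta_grid,
            class = "form_ladder")
}

#' @export
print.form_ladder <- function(x, ...) {
  cat(sprintf("Candidate short forms (%s objective):\n",
              x[[1L]]$formulation))
  for (f in x)
    cat(sprintf("  %2d items: {%s}  objective %.4f\n", f$length,
                paste(f$items, collapse = ", "), f$objective))
  invisible(x)
}
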