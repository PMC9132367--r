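#' Cronbach's alpha for an item subset
#'
#' \deqn{\alpha = \frac{k}{k-1}\Bigl(1 - \frac{\sum_j s_j^2}{s_T^2}\Bigr),}
#' with item variances \eqn{s_j^2} and total-score variance \eqn{s_T^2}
#' (sample variances, complete cases).
#'
#' @param responses respondent-by-item matrix.
#' @param subset item indices of the form (default all columns).
#' @return Alpha (can be negative for incoherent item sets).
#' @export
cronbach_alpha <- function(responses, subset = NULL) {
  x <- as.matrix(responses)
  if (is.null(subset)) subset <- seq_len(ncol(x))
  subset <- check_subset(subset, ncol(x))
  x <- x[stats::complete.cases(x[, subset, drop = FALSE]), subset, drop = FALSE]
  k <- ncol(x)
  if (k < 2L || nrow(x) < 2L) stop("need at least 2 items and 2 respondents")
  tot_var <- stats::var(rowSums(x))
  if (tot_var == 0) stop("total-score variance is zero; alpha undefined")
  k / (k - 1) * (1 - sum(apply(x, 2L, stats::var)) / tot_var)
}

#' Reliability-retention criterion
#'
#' Passes when the short form keeps at least `ratio` of the full form's
#' alpha.
#'
#' @param alpha_short,alpha_full Cronbach alphas.
#' @param ratio required retention fraction (default 0.95).
#' @return Logical.
#' @export
reliability_criterion <- function(alpha_short, alpha_full, ratio = 0.95) {
  if (alpha_full <= 0) stop("'alpha_full' must be positive")
  alpha_short >= ratio * alpha_full
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param scores_a,scores_b numeric vectors of equal length (>= 3), both
#'   with nonzero variance.
#' @param level confidence level (default 0.95).
#' @return List with `r`, `ci` (length 2) and `n`.
#' @export
concurrent_validity <- function(scores_a, scores_b, level = 0.95) {
  ok <- stats::complete.cases(scores_a, scores_b)
  a <- scores_a[ok]; b <- scores_b[ok]
  n <- length(a)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(a, b)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  list(r = r, ci = tanh(c(z - q * se, z + q * se)), n = n)
}

# Pearson-Filon / Steiger asymptotic covariance term for two correlations
# sharing one variable: n * cov(r13, r23)
overlap_cov <- function(r13, r23, r12) {
  r12 * (1 - r13^2 - r23^2) - 0.5 * r13 * r23 * (1 - r13^2 - r23^2 - r12^2)
}

#' Equivalence test for two overlapping dependent correlations
#'
#' Tests whether the convergent-validity correlation of a short form
#' (`r13`: short-form score vs external measure) is statistically
#' equivalent to that of the full form (`r23`: full-form score vs the same
#' external measure), the two correlations being dependent through the
#' short/full score correlation `r12`. Two one-sided z-tests (TOST) of
#' \eqn{H_0: |\rho_{13} - \rho_{23}| \ge \delta} are performed on the raw
#' correlation difference with the Pearson--Filon/Steiger asymptotic
#' variance of a difference of overlapping correlations; the TOST p-value
#' is the larger of the two one-sided p-values. Equivalence at level
#' \eqn{\alpha} is declared when p (after any multiplicity adjustment)
#' \eqn{\le \alpha}.
#'
#' @param r13,r23 correlations of the two forms with the shared external
#'   variable, each strictly inside (-1, 1).
#' @param r12 correlation between the two forms' scores.
#' @param n sample size (>= 10).
#' @param margin equivalence margin \eqn{\delta} on the raw correlation
#'   scale (default 0.05).
#' @return An object of class `equivalence_result`: `diff`, `se`, the two
#'   one-sided p-values `p_lower`, `p_upper`, and TOST `p`.
#' @examples
#' dependent_corr_equivalence(0.52, 0.56, 0.95, n = 2552)
#' @export
dependent_corr_equivalence <- function(r13, r23, r12, n, margin = 0.05) {
  if (n < 10L) stop("'n' must be at least 10")
  if (abs(r13) >= 1 || abs(r23) >= 1)
    stop("'r13' and 'r23' must be strictly inside (-1, 1)")
  if (margin <= 0 || margin > 1) stop("'margin' must be in (0, 1]")
  R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3L)
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("(r12, r13, r23) do not form a positive semidefinite correlation matrix")
  d <- r13 - r23
  v <- ((1 - r13^2)^2 + (1 - r23^2)^2 - 2 * overlap_cov(r13, r23, r12)) / n
  se <- sqrt(max(v, 0))
  if (se == 0) {
    p_lower <- p_upper <- as.numeric(abs(d) >= margin)
  } else {
    # H0a: d >= margin  vs  d < margin
    p_upper <- stats::pnorm((d - margin) / se)
    # H0b: d <= -margin vs  d > -margin
    p_lower <- stats::pnorm((d + margin) / se, lower.tail = FALSE)
  }
  structure(list(r13 = r13, r23 = r23, r12 = r12, n = n, margin = margin,
                 diff = d, se = se, p_lower = p_lower, p_upper = p_upper,
                 p = max(p_lower, p_upper)),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "TOST equivalence of dependent correlations: diff %.4f (margin %.3g, n %d), p = %.4g\n",
    x$diff, x$margin, x$n, x$p))
  invisible(x)
}

#' Benjamini--Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values
#' (a thin wrapper over [stats::p.adjust]).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Selection-criteria configuration
#'
#' @param alpha_retention_ratio required fraction of the full form's alpha
#'   (default 0.95).
#' @param concurrent_r_min required concurrent-validity correlation for both
#'   scorings (default 0.90).
#' @param equivalence_margin TOST margin on the raw correlation scale
#'   (default 0.05).
#' @param significance_level level applied to BH-adjusted equivalence
#'   p-values (default 0.05).
#' @return An object of class `criteria_config`.
#' @export
criteria_config <- function(alpha_retention_ratio = 0.95,
                            concurrent_r_min = 0.90,
                            equivalence_margin = 0.05,
                            significance_level = 0.05) {
  vals <- c(alpha_retention_ratio, concurrent_r_min, equivalence_margin,
            significance_level)
  if (any(vals <= 0 | vals > 1))
    stop("all criteria parameters must lie in (0, 1]")
  structure(list(alpha_retention_ratio = alpha_retention_ratio,
                 concurrent_r_min = concurrent_r_min,
                 equivalence_margin = equivalence_margin,
                 significance_level = significance_level),
            class = "criteria_config")
}

#' Build the per-length criteria table
#'
#' For each candidate short form (plus the full form as reference row) and
#' each external measure, computes Cronbach's alpha, concurrent-validity
#' correlations of summed and EAP factor scores with the full form,
#' convergent-validity correlations with the external measure for both
#' scorings, and the TOST equivalence p-values comparing each short form's
#' convergent validity to the full form's. Benjamini--Hochberg adjustment
#' is applied within one family per external measure (candidate lengths x
#' two scoring procedures); the full-form rows are degenerate
#' self-comparisons and are reported unadjusted outside the family.
#'
#' @param responses binary response matrix of the target measure
#'   (complete cases).
#' @param bank calibrated [item_bank] or [gpcm] fit for the target measure.
#' @param ladder a [candidate_ladder] of short forms.
#' @param external named list of external summed-score vectors (same
#'   respondents).
#' @param config a [criteria_config].
#' @param grid [trait_grid] used for EAP scoring.
#' @return A data frame of class `criteria_table` with one row per
#'   candidate length per external measure plus full-form reference rows.
#' @export
build_criteria_table <- function(responses, bank, ladder, external,
                                 config = criteria_config(),
                                 grid = trait_grid()) {
  x <- as.matrix(responses)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  bank <- as_item_bank(bank)
  p <- length(bank$a)
  if (is.null(names(external)) || any(names(external) == ""))
    stop("'external' must be a named list of score vectors")

  full_sum <- summed_scores(x)
  full_eap <- eap_scores(bank, x, grid = grid)
  alpha_full <- cronbach_alpha(x)
  n <- nrow(x)

  lens <- vapply(ladder, function(f) f$length, 1L)
  subsets <- lapply(ladder, function(f) f$items)
  # full form appended as the reference row
  lens <- c(lens, p)
  subsets <- c(subsets, list(seq_len(p)))

  rows <- list()
  for (ext_name in names(external)) {
    ext <- external[[ext_name]]
    if (length(ext) != n)
      stop(sprintf("external scores '%s' must have one value per complete case",
                   ext_name))
    r_full_sum_ext <- stats::cor(full_sum, ext)
    r_full_eap_ext <- stats::cor(full_eap, ext)
    tab <- data.frame(external = ext_name, length = lens, alpha = NA_real_,
                      r_sum_full = NA_real_, r_eap_full = NA_real_,
                      r_sum_ext = NA_real_, r_eap_ext = NA_real_,
                      p_sum = NA_real_, p_eap = NA_real_,
                      items = NA_character_)
    for (i in seq_along(lens)) {
      s <- subsets[[i]]
      ss <- summed_scores(x, s)
      fs <- eap_scores(bank, x, s, grid = grid)
      tab$alpha[i] <- cronbach_alpha(x, s)
      tab$r_sum_full[i] <- stats::cor(ss, full_sum)
      tab$r_eap_full[i] <- stats::cor(fs, full_eap)
      tab$r_sum_ext[i] <- stats::cor(ss, ext)
      tab$r_eap_ext[i] <- stats::cor(fs, ext)
      tab$p_sum[i] <- dependent_corr_equivalence(
        tab$r_sum_ext[i], r_full_sum_ext, tab$r_sum_full[i], n,
        config$equivalence_margin)$p
      tab$p_eap[i] <- dependent_corr_equivalence(
        tab$r_eap_ext[i], r_full_eap_ext, tab$r_eap_full[i], n,
        config$equivalence_margin)$p
      tab$items[i] <- paste(s, collapse = ",")
    }
    cand <- tab$length < p
    adj <- bh_adjust(c(tab$p_sum[cand], tab$p_eap[cand]))
    m <- sum(cand)
    tab$p_sum_adj <- tab$p_sum
    tab$p_eap_adj <- tab$p_eap
    tab$p_sum_adj[cand] <- adj[seq_len(m)]
    tab$p_eap_adj[cand] <- adj[m + seq_len(m)]
    rows[[ext_name]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$alpha_full <- alpha_full
  out$n <- n
  class(out) <- c("criteria_table", "data.frame")
  out
}

#' Select the final short form by the five prespecified criteria
#'
#' Returns the shortest candidate length that simultaneously (1) retains
#' the required fraction of the full form's alpha, (2, 3) correlates at
#' least `concurrent_r_min` with the full form under both summed and factor
#' scoring, and (4, 5) shows BH-adjusted TOST equivalence of its convergent
#' validity with the full form's for both scorings. If no candidate passes
#' all five, the full form is returned with `admissible = FALSE`.
#'
#' @param table a [build_criteria_table] result (or a data frame with the
#'   same columns).
#' @param config a [criteria_config].
#' @param external_measure which external measure's rows to use (default:
#'   the first present).
#' @return List with `length`, `items` (NULL for rows without item sets),
#'   `admissible`, and the per-criterion pass table `checks`.
#' @export
select_final_form <- function(table, config = criteria_config(),
                              external_measure = NULL) {
  tab <- as.data.frame(table)
  if (is.null(external_measure)) external_measure <- tab$external[1L]
  tab <- tab[tab$external == external_measure, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no rows for the requested external measure")
  full_len <- max(tab$length)
  alpha_full <- tab$alpha[tab$length == full_len][1L]
  cand <- tab[tab$length < full_len, , drop = FALSE]
  cand <- cand[order(cand$length), , drop = FALSE]
  checks <- data.frame(
    length = cand$length,
    reliability = cand$alpha >= config$alpha_retention_ratio * alpha_full,
    concurrent_sum = cand$r_sum_full >= config$concurrent_r_min,
    concurrent_eap = cand$r_eap_full >= config$concurrent_r_min,
    equivalence_sum = cand$p_sum_adj <= config$significance_level,
    equivalence_eap = cand$p_eap_adj <= config$significance_level)
  pass <- checks$reliability & checks$concurrent_sum & checks$concurrent_eap &
    checks$equivalence_sum & checks$equivalence_eap
  if (any(pass)) {
    i <- which(pass)[1L]
    items <- if (!is.null(cand$items))
      as.integer(strsplit(cand$items[i], ",")[[1L]]) else NULL
    list(length = checks$length[i], items = items, admissible = TRUE,
         external = external_measure, checks = checks)
  } else {
    list(length = full_len, items = seq_len(full_len), admissible = FALSE,
         external = external_measure, checks = checks)
  }
}
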