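#' Group means with confidence intervals
#'
#' Mean score per level of a grouping variable with a normal-approximation
#' confidence interval (mean +/- z * SE); a t-based interval is available
#' via `method = "t"`. Levels with fewer than two observations are reported
#' with `NA` intervals.
#'
#' @param scores numeric vector.
#' @param grouping factor or character vector of the same length.
#' @param level confidence level (default 0.95).
#' @param method `"normal"` (default) or `"t"`.
#' @return A data frame of class `group_summary`: level, n, mean, lower,
#'   upper.
#' @export
group_means <- function(scores, grouping, level = 0.95,
                        method = c("normal", "t")) {
  method <- match.arg(method)
  if (length(grouping) != length(scores))
    stop("'scores' and 'grouping' must have the same length")
  ok <- !is.na(scores) & !is.na(grouping)
  scores <- scores[ok]; grouping <- factor(grouping[ok])
  if (length(scores) == 0L) stop("no non-missing observations to summarize")
  out <- do.call(rbind, lapply(levels(grouping), function(g) {
    v <- scores[grouping == g]
    n <- length(v); m <- mean(v)
    if (n >= 2L) {
      se <- stats::sd(v) / sqrt(n)
      q <- if (method == "normal") stats::qnorm(1 - (1 - level) / 2)
           else stats::qt(1 - (1 - level) / 2, df = n - 1L)
      data.frame(level = g, n = n, mean = m, lower = m - q * se,
                 upper = m + q * se)
    } else {
      data.frame(level = g, n = n, mean = m, lower = NA_real_,
                 upper = NA_real_)
    }
  }))
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Dichotomize the perceived-accuracy item
#'
#' Collapses the 5-level perceived-accuracy response (1 = completely
#' inaccurate ... 4 = completely accurate, plus "don't know") into
#' "completely accurate" (level 4) versus everything else.
#'
#' @param perception vector with levels `"1"`-`"4"` and `"dont_know"`.
#' @return Factor with levels `"completely_accurate"`, `"not_completely_accurate"`.
#' @export
dichotomize_uu <- function(perception) {
  x <- as.character(perception)
  valid <- c("1", "2", "3", "4", "dont_know")
  bad <- !is.na(x) & !x %in% valid
  if (any(bad))
    stop(sprintf("unknown perception level(s): %s",
                 paste(unique(x[bad]), collapse = ", ")))
  out <- ifelse(is.na(x), NA_character_,
                ifelse(x == "4", "completely_accurate",
                       "not_completely_accurate"))
  factor(out, levels = c("completely_accurate", "not_completely_accurate"))
}

#' Descriptive statistics table
#'
#' Counts and percentages per level for categorical variables, mean/SD and
#' median/IQR for continuous ones.
#'
#' @param data a data frame (e.g. the `covariates` of a
#'   [generate_population] dataset) or a `synthetic_dataset`.
#' @return List with `categorical` (variable, level, n, pct) and
#'   `continuous` (variable, mean, sd, median, q1, q3) data frames.
#' @export
descriptive_table <- function(data) {
  if (inherits(data, "synthetic_dataset")) {
    df <- data$covariates
    df$score_main <- summed_scores(data$responses_main)
    df$score_kq <- summed_scores(data$responses_kq)
    df$score_who <- summed_scores(data$responses_who)
  } else df <- as.data.frame(data)
  cat_rows <- list(); cont_rows <- list()
  for (v in names(df)) {
    col <- df[[v]]
    if (is.numeric(col)) {
      cont_rows[[v]] <- data.frame(
        variable = v, mean = mean(col, na.rm = TRUE),
        sd = stats::sd(col, na.rm = TRUE),
        median = stats::median(col, na.rm = TRUE),
        q1 = unname(stats::quantile(col, 0.25, na.rm = TRUE)),
        q3 = unname(stats::quantile(col, 0.75, na.rm = TRUE)))
    } else {
      f <- factor(col)
      tb <- table(f)
      cat_rows[[v]] <- data.frame(variable = v, level = names(tb),
                                  n = as.integer(tb),
                                  pct = 100 * as.integer(tb) / sum(tb))
    }
  }
  list(categorical = if (length(cat_rows)) do.call(rbind, c(cat_rows, make.row.names = FALSE)) else NULL,
       continuous = if (length(cont_rows)) do.call(rbind, c(cont_rows, make.row.names = FALSE)) else NULL)
}

#' Known-groups validity check
#'
#' Evaluates ordered group-mean hypotheses (e.g. education: middle school
#' below high school below college) on the point estimates of a
#' [group_means] summary. The result is a labeled pass/fail on the observed
#' ordering, not an inferential claim.
#'
#' @param summary a `group_summary`.
#' @param ordering character vector of levels in hypothesized increasing
#'   order of mean score.
#' @return List with `pass` and the observed `means` in hypothesis order.
#' @export
known_groups_check <- function(summary, ordering) {
  miss <- setdiff(ordering, summary$level)
  if (length(miss))
    stop(sprintf("hypothesis references absent level(s): %s",
                 paste(miss, collapse = ", ")))
  m <- summary$mean[match(ordering, summary$level)]
  list(pass = all(diff(m) > 0), means = stats::setNames(m, ordering))
}
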