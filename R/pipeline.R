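#' Read a response/covariate CSV
#'
#' Reads a rectangular CSV in the layout written by [write_dataset]
#' (an `id` column, binary response columns, then covariates), validates
#' response coding, and flags incomplete rows. Blank cells are missing.
#'
#' @param path CSV path.
#' @param response_prefixes column-name prefixes identifying response
#'   blocks (default `c("item", "kq", "who")`).
#' @return List with response matrices per prefix, `covariates`,
#'   `complete` (logical: complete on every response block), and counts
#'   `n_total`, `n_complete`.
#' @export
read_responses <- function(path, response_prefixes = c("item", "kq", "who")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("missing 'id' column")
  if (anyDuplicated(df$id)) stop("duplicate respondent ids")
  resp <- list()
  used <- "id"
  for (pre in response_prefixes) {
    cols <- grep(paste0("^", pre, "[0-9]+$"), names(df), value = TRUE)
    if (length(cols) == 0L) next
    m <- as.matrix(df[cols])
    bad <- which(!(is.na(m) | m == 0 | m == 1), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("unknown response code at row %d, column '%s'",
                   bad[1L, 1L], cols[bad[1L, 2L]]))
    storage.mode(m) <- "integer"
    resp[[pre]] <- m
    used <- c(used, cols)
  }
  if (length(resp) == 0L) stop("no response columns found")
  covs <- df[setdiff(names(df), used)]
  complete <- Reduce(`&`, lapply(resp, function(m) stats::complete.cases(m)))
  message(sprintf("read %d rows; %d complete on all response blocks (%d excluded)",
                  nrow(df), sum(complete), sum(!complete)))
  c(resp, list(covariates = covs, complete = complete,
               n_total = nrow(df), n_complete = sum(complete)))
}

#' Run the full short-form development pipeline
#'
#' Orchestrates the whole analysis on a synthetic (or supplied) dataset:
#' split-sample dimensionality screening, GPCM calibration on the full
#' sample, assembly of the candidate short-form ladder, evaluation of the
#' five selection criteria against both external measures, selection of the
#' final form per external measure, and known-groups/convergent validity
#' profiling of the selected forms.
#'
#' @param config a [generator_config] (a dataset is generated), or a
#'   `synthetic_dataset` / compatible list with elements `responses_main`,
#'   `responses_kq`, `responses_who` and `covariates`.
#' @param anchors an [anchor_set].
#' @param criteria a [criteria_config].
#' @param formulation assembly objective, `"sum"` or `"maximin"`.
#' @param split_seed seed for the dimensionality split.
#' @param screen run the dimensionality screen (default TRUE; it is the
#'   slowest descriptive stage and can be skipped in simulation studies).
#' @return An object of class `run_report`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(generator_config(n_respondents = 600, seed = 3),
#'                     screen = FALSE)
#' rep$selected$kq$length
#' }
#' @export
run_pipeline <- function(config = generator_config(),
                         anchors = anchor_set(),
                         criteria = criteria_config(),
                         formulation = c("sum", "maximin"),
                         split_seed = 1L, screen = TRUE) {
  formulation <- match.arg(formulation)
  dataset <- if (inherits(config, "generator_config"))
    generate_population(config) else config
  x <- dataset$responses_main
  keep <- stats::complete.cases(x, dataset$responses_kq, dataset$responses_who)
  x <- x[keep, , drop = FALSE]

  scr <- if (screen) dimensionality_screen(x, seed = split_seed) else NULL

  fit <- gpcm(x)
  ladder <- candidate_ladder(fit, anchors, formulation)

  external <- list(
    kq = summed_scores(dataset$responses_kq[keep, , drop = FALSE]),
    who = summed_scores(dataset$responses_who[keep, , drop = FALSE]))
  tab <- build_criteria_table(x, fit, ladder, external, criteria,
                              grid = fit$grid)
  selected <- lapply(names(external), function(m)
    select_final_form(tab, criteria, m))
  names(selected) <- names(external)

  covs <- dataset$covariates[keep, , drop = FALSE]
  profiles <- lapply(selected, function(sel) {
    sc <- summed_scores(x, sel$items)
    out <- list()
    if (!is.null(covs$uu_perception))
      out$uu <- group_means(sc, dichotomize_uu(covs$uu_perception))
    for (v in intersect(c("age_band", "race", "education", "income",
                          "hiv_test", "prep_use"), names(covs)))
      out[[v]] <- group_means(sc, covs[[v]])
    out
  })

  structure(list(
    screen = scr, fit = fit, ladder = ladder, criteria_table = tab,
    selected = selected, profiles = profiles,
    descriptives = descriptive_table(
      if (inherits(dataset, "synthetic_dataset")) dataset else covs),
    provenance = list(
      seeds = list(
        generator = if (inherits(dataset, "synthetic_dataset")) dataset$seed else NA,
        split = split_seed),
      n_analytic = nrow(x), anchors = anchors, formulation = formulation,
      criteria = unclass(criteria),
      package_version = as.character(utils::packageVersion("shortform")))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Short-form development report\n")
  cat(sprintf("  analytic n = %d; GPCM %s after %d EM iterations\n",
              x$provenance$n_analytic,
              if (x$fit$converged) "converged" else "NOT converged",
              x$fit$iter))
  if (!is.null(x$screen))
    cat(sprintf("  dimensionality screen: first eigenvalue %.2f (%s)\n",
                x$screen$eigenvalues[1L],
                if (x$screen$one_factor) "one factor" else "not clearly one factor"))
  for (m in names(x$selected)) {
    s <- x$selected[[m]]
    cat(sprintf("  vs %s: %s form of %d items {%s}\n", m,
                if (s$admissible) "selected short" else "no admissible short form; full",
                s$length, paste(s$items, collapse = ", ")))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes the criteria table and group summaries as CSV and the whole
#' report (including provenance: seeds, configuration, package version) as
#' JSON. Numeric fields are serialized at full precision; display rounding
#' is the reader's concern.
#'
#' @param report a [run_pipeline] result.
#' @param dir output directory (created if needed).
#' @param formats any of `"csv"`, `"json"`.
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, dir, formats = c("csv", "json")) {
  stopifnot(inherits(report, "run_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if ("csv" %in% formats) {
    p <- file.path(dir, "criteria_table.csv")
    utils::write.csv(as.data.frame(report$criteria_table), p, row.names = FALSE)
    paths <- c(paths, p)
    for (m in names(report$profiles)) {
      prof <- do.call(rbind, lapply(names(report$profiles[[m]]), function(v)
        cbind(variable = v, as.data.frame(report$profiles[[m]][[v]]))))
      p <- file.path(dir, sprintf("profiles_%s.csv", m))
      utils::write.csv(prof, p, row.names = FALSE)
      paths <- c(paths, p)
    }
    if (!is.null(report$descriptives$categorical)) {
      p <- file.path(dir, "descriptives.csv")
      utils::write.csv(report$descriptives$categorical, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    payload <- list(
      criteria_table = as.data.frame(report$criteria_table),
      selected = lapply(report$selected, function(s)
        list(length = s$length, items = s$items, admissible = s$admissible)),
      item_parameters = list(a = report$fit$bank$a, b = report$fit$bank$b),
      descriptives = report$descriptives,
      provenance = report$provenance)
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor", force = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
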