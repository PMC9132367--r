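#' Item-bank specification for the synthetic generator
#'
#' Describes, per measure, how many items to draw and the uniform ranges
#' for GPCM discriminations and (binary) thresholds. The defaults emulate a
#' 12-item target knowledge measure plus a 15-item and a 5-item convergent
#' measure answered by a knowledgeable population: thresholds are strongly
#' negative, so most items are easy and summed scores pile up near the
#' ceiling (full-scale mean around 11 of 12), while discriminations span a
#' wide range so that a few items dominate the test information function.
#'
#' @param n_items integer item counts per measure.
#' @param disc_range positive length-2 range for uniform discriminations.
#' @param thresh_range length-2 range for uniform thresholds; negative
#'   values make items easy.
#' @return A named list of per-measure specifications.
#' @export
default_bank_spec <- function(n_items = c(main = 12L, kq = 15L, who = 5L),
                              disc_range = c(0.9, 2.5),
                              thresh_range = c(-3.4, -1.2)) {
  if (any(n_items < 3L)) stop("each measure needs at least 3 items")
  if (length(disc_range) != 2L || any(disc_range <= 0) ||
      disc_range[1] > disc_range[2])
    stop("'disc_range' must be a positive nondecreasing length-2 range")
  if (length(thresh_range) != 2L || thresh_range[1] > thresh_range[2])
    stop("'thresh_range' must be a nondecreasing length-2 range")
  lapply(n_items, function(k)
    list(n_items = as.integer(k), disc_range = disc_range,
         thresh_range = thresh_range))
}

#' Draw random GPCM item banks
#'
#' Samples, for each measure in the specification, item discriminations and
#' thresholds uniformly from the configured ranges. With a degenerate range
#' (equal endpoints) all items get exactly that value.
#'
#' @param spec a specification as returned by [default_bank_spec].
#' @param seed optional integer seed; identical spec + seed gives identical
#'   banks.
#' @return A named list of [item_bank] objects.
#' @examples
#' banks <- generate_item_bank(seed = 1)
#' banks$main
#' @export
generate_item_bank <- function(spec = default_bank_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(spec, function(s) {
    if (any(s$disc_range <= 0))
      stop("discrimination range must be strictly positive")
    if (s$n_items < 3L) stop("each measure needs at least 3 items")
    item_bank(a = stats::runif(s$n_items, s$disc_range[1], s$disc_range[2]),
              b = stats::runif(s$n_items, s$thresh_range[1], s$thresh_range[2]))
  })
  names(out) <- names(spec)
  out
}

#' Simulate categorical responses from a GPCM item bank
#'
#' Draws each response from the GPCM category distribution at the
#' respondent's latent trait value.
#'
#' @param bank an [item_bank].
#' @param theta numeric vector of latent traits, one per respondent.
#' @param seed optional integer seed.
#' @return Integer matrix, `length(theta)` rows by `length(bank)` columns,
#'   with entries in `0..K_j - 1`.
#' @export
simulate_responses <- function(bank, theta, seed = NULL) {
  bank <- as_item_bank(bank)
  if (length(theta) < 1L || any(!is.finite(theta)))
    stop("'theta' must be a nonempty finite vector")
  if (!is.null(seed)) set.seed(seed)
  n <- length(theta); p <- length(bank$a)
  x <- matrix(0L, n, p, dimnames = list(NULL, bank$items))
  for (j in seq_len(p)) {
    P <- gpcm_prob(theta, bank$a[j], bank$b[[j]])
    if (ncol(P) == 2L) {
      x[, j] <- stats::rbinom(n, 1L, P[, 2L])
    } else {
      cum <- t(apply(P, 1L, cumsum))
      u <- stats::runif(n)
      x[, j] <- rowSums(u > cum[, -ncol(cum), drop = FALSE])
    }
  }
  x
}

# fixed level vocabularies and study-like marginal frequencies
covariate_levels <- function() {
  list(age_band   = c("18-24", "25-34", "35-44", "45-54", "55+"),
       race       = c("white", "pardo", "black", "asian", "indigenous",
                      "not_declared"),
       education  = c("middle_school", "high_school", "college"),
       income     = c("low", "middle", "high"),
       hiv_test   = c("never", "negative", "positive"),
       prep_use   = c("never", "current", "past"),
       condomless = c("yes", "no"),
       art_adherent = c("yes", "no"),
       uu_perception = c("dont_know", "1", "2", "3", "4"))
}

covariate_marginals <- function() {
  list(age_band  = c(0.126, 0.419, 0.283, 0.122, 0.050),
       race      = c(0.565, 0.292, 0.116, 0.011, 0.007, 0.009),
       education = c(0.039, 0.265, 0.696),
       income    = c(0.295, 0.446, 0.259),
       hiv_test  = c(0.098, 0.592, 0.310),
       prep_use  = c(0.802, 0.128, 0.070),
       condomless = c(0.407, 0.593),
       art_adherent = c(0.601, 0.399))
}

#' Default covariate effects on the latent knowledge trait
#'
#' Latent-trait shifts (in SD units) per covariate level. The defaults
#' encode the knowledge gradients the generator is meant to emulate: lower
#' education, lower income, youngest and oldest age bands, never having
#' tested for HIV and never having used PrEP sit below the mean; college
#' education, current PrEP use and a positive test status sit above it.
#' Effects are centered at generation time so they move groups apart
#' without shifting the population mean.
#'
#' @return Named list of named numeric vectors.
#' @export
default_covariate_effects <- function() {
  list(age_band  = c("18-24" = -0.35, "25-34" = 0.05, "35-44" = 0.05,
                     "45-54" = 0.00, "55+" = -0.25),
       race      = c(white = 0.08, pardo = -0.10, black = -0.10, asian = 0.08,
                     indigenous = -0.10, not_declared = 0),
       education = c(middle_school = -0.70, high_school = -0.30, college = 0.15),
       income    = c(low = -0.30, middle = 0.05, high = 0.12),
       hiv_test  = c(never = -0.65, negative = 0.00, positive = 0.20),
       prep_use  = c(never = -0.05, current = 0.35, past = 0.05),
       condomless = c(yes = 0, no = 0),
       art_adherent = c(yes = 0.05, no = 0))
}

#' Configuration for the synthetic-data generator
#'
#' @param n_respondents sample size (default 2552).
#' @param bank_spec item-bank specification, see [default_bank_spec].
#' @param trait_cor either a single inter-trait correlation (default 0.82)
#'   or a full 3x3 correlation matrix for the latent traits underlying the
#'   three measures.
#' @param covariate_effects named list of per-level trait shifts in SD
#'   units, see [default_covariate_effects]; set all to 0 for a null
#'   configuration.
#' @param missing_rate probability in `[0, 1)` that a response entry is
#'   missing completely at random (default 0: the analytic set emulates
#'   complete responders).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of config + seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_respondents = 2552L,
                             bank_spec = default_bank_spec(),
                             trait_cor = 0.82,
                             covariate_effects = default_covariate_effects(),
                             missing_rate = 0,
                             seed = 1L) {
  n <- as.integer(n_respondents)
  if (n < 2L) stop("'n_respondents' must be a positive integer >= 2")
  if (is.matrix(trait_cor)) {
    R <- trait_cor
  } else {
    R <- matrix(trait_cor, 3L, 3L); diag(R) <- 1
  }
  if (nrow(R) != 3L || ncol(R) != 3L || any(abs(R - t(R)) > 1e-12) ||
      any(abs(diag(R) - 1) > 1e-12))
    stop("'trait_cor' must give a symmetric 3x3 correlation matrix with unit diagonal")
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 1e-10))
    stop("trait correlation matrix must be positive definite")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must be in [0, 1)")
  structure(list(n_respondents = n, bank_spec = bank_spec, trait_cor = R,
                 covariate_effects = covariate_effects,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a seeded synthetic survey dataset
#'
#' Produces a full synthetic analogue of a cross-sectional HIV-knowledge
#' survey: correlated latent knowledge traits for three measures, binary
#' responses drawn from per-measure GPCM item banks, categorical covariates
#' with study-like marginal frequencies, covariate-driven knowledge
#' gradients, and a 5-category perceived-accuracy item generated from the
#' main trait through an ordered-logistic link (with "don't know" as the
#' lowest, low-trait-favoring category).
#'
#' Covariate effects are centered within each covariate, so they create
#' group contrasts in the configured directions without moving the
#' population trait mean. PrEP use and condomless sex apply only to
#' HIV-negative/never-tested respondents and treatment adherence only to
#' HIV-positive respondents; the remaining cells are `NA`.
#'
#' @param config a [generator_config].
#' @return An object of class `synthetic_dataset`: binary response matrices
#'   `responses_main` (n x 12), `responses_kq` (n x 15), `responses_who`
#'   (n x 5), a `covariates` data frame, the `true_theta` n x 3 matrix, the
#'   true item `banks`, and the `config`.
#' @examples
#' d <- generate_population(generator_config(n_respondents = 300, seed = 7))
#' mean(summed_scores(d$responses_main))
#' @export
generate_population <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    stop("'config' must be a generator_config")
  set.seed(config$seed)
  n <- config$n_respondents
  lev <- covariate_levels()
  marg <- covariate_marginals()

  banks <- generate_item_bank(config$bank_spec)

  draw <- function(name, size = n)
    factor(sample(lev[[name]], size, replace = TRUE, prob = marg[[name]]),
           levels = lev[[name]])
  cov <- data.frame(age_band = draw("age_band"), race = draw("race"),
                    education = draw("education"), income = draw("income"),
                    hiv_test = draw("hiv_test"))
  neg <- cov$hiv_test != "positive"
  cov$prep_use <- factor(NA_character_, levels = lev$prep_use)
  cov$prep_use[neg] <- draw("prep_use", sum(neg))
  cov$condomless <- factor(NA_character_, levels = lev$condomless)
  cov$condomless[neg] <- draw("condomless", sum(neg))
  cov$art_adherent <- factor(NA_character_, levels = lev$art_adherent)
  cov$art_adherent[!neg] <- draw("art_adherent", sum(!neg))

  # centered covariate-driven trait shifts
  shift <- numeric(n)
  for (v in names(config$covariate_effects)) {
    if (!v %in% names(cov)) next
    eff <- config$covariate_effects[[v]][as.character(cov[[v]])]
    eff[is.na(eff)] <- 0
    shift <- shift + (eff - mean(eff))
  }

  # residual variance shrunk so the total trait variance stays ~1 and the
  # configured shifts read as fractions of the trait SD
  resid_sd <- sqrt(max(1 - stats::var(shift), 0.05))
  L <- chol(config$trait_cor)
  theta <- resid_sd * matrix(stats::rnorm(n * 3L), n, 3L) %*% L + shift
  colnames(theta) <- c("main", "kq", "who")

  responses <- list(main = simulate_responses(banks$main, theta[, 1L]),
                    kq   = simulate_responses(banks$kq, theta[, 2L]),
                    who  = simulate_responses(banks$who, theta[, 3L]))
  colnames(responses$main) <- sprintf("item%02d", seq_len(ncol(responses$main)))
  colnames(responses$kq) <- sprintf("kq%02d", seq_len(ncol(responses$kq)))
  colnames(responses$who) <- sprintf("who%02d", seq_len(ncol(responses$who)))

  if (config$missing_rate > 0) {
    for (m in names(responses)) {
      mask <- matrix(stats::runif(length(responses[[m]])) < config$missing_rate,
                     nrow(responses[[m]]))
      responses[[m]][mask] <- NA_integer_
    }
  }

  # perceived accuracy of the U=U message: ordered logit on the main trait,
  # cutpoints set so ~63% land in "completely accurate" at trait 0
  cum0 <- c(0.08, 0.13, 0.21, 0.37)
  eta <- 1.2 * theta[, 1L]
  cump <- stats::plogis(outer(stats::qlogis(cum0), eta, `-`))  # 4 x n
  u <- stats::runif(n)
  idx <- 1L + colSums(cump < matrix(u, 4L, n, byrow = TRUE))
  cov$uu_perception <- factor(lev$uu_perception[idx], levels = lev$uu_perception)

  structure(list(responses_main = responses$main, responses_kq = responses$kq,
                 responses_who = responses$who, covariates = cov,
                 true_theta = theta, banks = banks, config = config,
                 seed = config$seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic knowledge-survey dataset: n = %d (seed %d)\n",
              nrow(x$covariates), x$seed))
  cm <- x$responses_main
  cc <- stats::complete.cases(cm)
  cat(sprintf("  12-item summed score: mean %.2f (SD %.2f) on %d complete cases\n",
              mean(rowSums(cm[cc, , drop = FALSE])),
              stats::sd(rowSums(cm[cc, , drop = FALSE])), sum(cc)))
  invisible(x)
}

#' Write / read a synthetic dataset
#'
#' `write_dataset` writes one rectangular CSV (respondent id, response
#' columns `item01..`, `kq01..`, `who01..`, then covariates) plus a JSON
#' sidecar holding the true item parameters and the generator
#' configuration. `read_generator_config` reads a configuration from YAML
#' or JSON.
#'
#' @param dataset a `synthetic_dataset`.
#' @param csv_path output CSV path.
#' @param json_path output path of the truth/config sidecar (default: the
#'   CSV path with extension `.json`).
#' @return `write_dataset` returns the paths invisibly.
#' @export
write_dataset <- function(dataset, csv_path,
                          json_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  df <- data.frame(id = seq_len(nrow(dataset$covariates)),
                   dataset$responses_main, dataset$responses_kq,
                   dataset$responses_who, dataset$covariates)
  utils::write.csv(df, csv_path, row.names = FALSE, na = "")
  truth <- list(
    banks = lapply(dataset$banks, function(bk)
      list(a = bk$a, b = lapply(bk$b, identity))),
    config = list(n_respondents = dataset$config$n_respondents,
                  trait_cor = dataset$config$trait_cor,
                  covariate_effects = dataset$config$covariate_effects,
                  missing_rate = dataset$config$missing_rate,
                  seed = dataset$config$seed))
  jsonlite::write_json(truth, json_path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(c(csv = csv_path, json = json_path))
}

#' @param path a YAML (`.yml`/`.yaml`) or JSON configuration file with any
#'   of the [generator_config] fields.
#' @rdname write_dataset
#' @export
read_generator_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  args <- list()
  for (f in c("n_respondents", "trait_cor", "missing_rate", "seed"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$trait_cor) && is.list(raw$trait_cor))
    args$trait_cor <- do.call(rbind, raw$trait_cor)
  if (!is.null(raw$covariate_effects))
    args$covariate_effects <- lapply(raw$covariate_effects, unlist)
  if (!is.null(raw$bank_spec)) {
    bs <- default_bank_spec()
    for (m in names(raw$bank_spec)) {
      for (f in names(raw$bank_spec[[m]]))
        bs[[m]][[f]] <- unlist(raw$bank_spec[[m]][[f]])
    }
    args$bank_spec <- bs
  }
  do.call(generator_config, args)
}
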