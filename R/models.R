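#' Read / write a cohort covariate table (TSV)
#'
#' Columns: `subject`, `group` (`psychopathic` / `control`), `site`,
#' `age` (years), `icv` (intracranial volume), and PCL-R scores
#' `pclr_total`, `pclr_f1`, `pclr_f2` (empty for controls, whose scores
#' were not assessed).
#'
#' @param path File path.
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject = readr::col_character(),
    group = readr::col_character(),
    site = readr::col_character(),
    .default = readr::col_double()))
}

#' @rdname read_cohort
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(path)
}

# design matrix shared by all per-region models.  Site enters as
# treatment-coded dummies with the largest site as reference; inference
# on the terms of interest is invariant to this coding.
build_design <- function(cohort, analysis) {
  cohort <- tibble::as_tibble(cohort)
  required <- switch(analysis,
    group   = c("group", "site", "age", "icv"),
    factors = c("pclr_f1", "pclr_f2", "site", "age", "icv"),
    total   = c("pclr_total", "site", "age", "icv"),
    stop("unknown analysis: ", analysis, call. = FALSE))
  missing_col <- setdiff(c("subject", required), names(cohort))
  if (length(missing_col) > 0) {
    stop("cohort table is missing column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  if (analysis %in% c("factors", "total")) {
    cohort <- cohort[cohort$group == "psychopathic", , drop = FALSE]
    if (nrow(cohort) == 0) {
      stop("no psychopathic subjects: PCL-R models are fitted within the ",
           "psychopathic group only", call. = FALSE)
    }
  }
  keep <- stats::complete.cases(cohort[, required, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropping ", n_dropped,
            " subject(s) with missing required covariates")
  }
  cohort <- cohort[keep, , drop = FALSE]

  site <- factor(cohort$site)
  site <- stats::relevel(site, ref = names(which.max(table(site))))
  df <- data.frame(site = site, age = cohort$age, icv = cohort$icv)
  terms_of_interest <- switch(analysis,
    group = {
      if (length(unique(cohort$group)) < 2) {
        stop("both groups must be present for the group model", call. = FALSE)
      }
      df$group_psychopathic <- as.numeric(cohort$group == "psychopathic")
      "group_psychopathic"
    },
    factors = {
      df$pclr_f1 <- cohort$pclr_f1
      df$pclr_f2 <- cohort$pclr_f2
      c("pclr_f1", "pclr_f2")
    },
    total = {
      df$pclr_total <- cohort$pclr_total
      "pclr_total"
    })
  covars <- c(if (nlevels(site) >= 2) "site", "age", "icv")
  form <- stats::reformulate(c(terms_of_interest, covars))
  X <- stats::model.matrix(form, data = df)
  list(X = X, subjects = cohort$subject, terms = terms_of_interest,
       n_dropped = n_dropped)
}

check_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  if (nrow(X) <= ncol(X)) {
    stop("insufficient data: ", nrow(X), " subjects for ", ncol(X),
         " design columns", call. = FALSE)
  }
  qrX
}

#' Fit per-region covariate-adjusted linear models
#'
#' Ordinary least squares of region volume on the predictor(s) of
#' interest plus the nuisance covariates study site, age and ICV:
#' * `analysis = "group"`: volume ~ group + site + age + ICV over all
#'   subjects; reports the psychopathic-vs-control coefficient and the
#'   group difference as a percentage of the adjusted control mean.
#' * `analysis = "factors"`: volume ~ PCL-R factor 1 + factor 2 + site +
#'   age + ICV within the psychopathic group — one joint model, so each
#'   factor is tested after adjustment for the other.
#' * `analysis = "total"`: as `"factors"` with the PCL-R total score as
#'   the single score predictor.
#'
#' All regions are fitted against the same design in a single
#' matrix-response [stats::lm()] call.  Subjects with any missing
#' required covariate are dropped listwise (with a message).
#'
#' @param volumes Volume table: tibble with `subject` plus one numeric
#'   column per region (mm^3).
#' @param cohort Cohort covariate table (see [read_cohort()]).
#' @param analysis One of `"group"`, `"factors"`, `"total"`.
#' @param regions Regions to fit (default: all volume columns).
#' @return A `region_results` tibble with columns `region`, `analysis`,
#'   `term`, `estimate` (mm^3 per predictor unit; mm^3 for group), `t`,
#'   `p` (two-sided), `df_resid`, `percent_diff` (group analysis only).
#' @export
#' @examples
#' study <- simulate_study(simulation_config(seed = 1), toy_hierarchy())
#' fit_region_models(study$volumes, study$cohort, "group")
fit_region_models <- function(volumes, cohort,
                              analysis = c("group", "factors", "total"),
                              regions = NULL) {
  analysis <- match.arg(analysis)
  volumes <- tibble::as_tibble(volumes)
  if (is.null(regions)) regions <- setdiff(names(volumes), "subject")
  absent <- setdiff(regions, names(volumes))
  if (length(absent) > 0) {
    stop("region(s) not in volume table: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  des <- build_design(cohort, analysis)
  idx <- match(des$subjects, volumes$subject)
  if (anyNA(idx)) {
    stop("subject(s) in cohort but not in volume table: ",
         paste(des$subjects[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  X <- des$X
  qrX <- check_rank(X)
  Y <- as.matrix(volumes[idx, regions, drop = FALSE])

  fit <- stats::lm(Y ~ X - 1)
  beta <- as.matrix(stats::coef(fit))
  rownames(beta) <- colnames(X)
  res <- as.matrix(stats::residuals(fit))
  df_resid <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / df_resid

  R <- qr.R(qrX)
  xtx_inv <- matrix(NA_real_, ncol(X), ncol(X))
  piv <- qrX$pivot
  xtx_inv[piv, piv] <- chol2inv(R)

  rows <- lapply(des$terms, function(term) {
    j <- match(term, colnames(X))
    se <- sqrt(xtx_inv[j, j] * s2)
    tval <- beta[j, ] / se
    pval <- 2 * stats::pt(-abs(tval), df_resid)
    pd <- rep(NA_real_, length(regions))
    if (analysis == "group") {
      X0 <- X
      X0[, j] <- 0
      pd <- 100 * beta[j, ] / colMeans(X0 %*% beta)
    }
    tibble::tibble(region = regions, analysis = analysis, term = term,
                   estimate = unname(beta[j, ]), t = unname(tval),
                   p = unname(pval), df_resid = df_resid,
                   percent_diff = unname(pd))
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, match(.data$region, regions), .data$term)
  structure(out, class = c("region_results", class(out)),
            analysis = analysis, n = nrow(X), n_dropped = des$n_dropped)
}

#' Single-region model fits
#'
#' Convenience wrappers around [fit_region_models()] for one region.
#' `fit_group_model()` returns one row (the group effect),
#' `fit_factor_model()` two rows (PCL-R factor 1 and factor 2, from one
#' joint model), `fit_total_model()` one row (PCL-R total).
#'
#' @inheritParams fit_region_models
#' @param region A region name present in `volumes`.
#' @return A `region_results` tibble (see [fit_region_models()]).
#' @export
fit_group_model <- function(volumes, cohort, region) {
  fit_region_models(volumes, cohort, "group", regions = region)
}

#' @rdname fit_group_model
#' @export
fit_factor_model <- function(volumes, cohort, region) {
  fit_region_models(volumes, cohort, "factors", regions = region)
}

#' @rdname fit_group_model
#' @export
fit_total_model <- function(volumes, cohort, region) {
  fit_region_models(volumes, cohort, "total", regions = region)
}

#' One-way ANOVA reconstructed from group summaries
#'
#' Recovers the F test for equality of group means from per-group mean,
#' SD and n alone: the between-group sum of squares from the means and
#' sizes, the within-group sum of squares from the SDs.  Useful for
#' checking published summary tables.
#'
#' @param groups Data frame with columns `mean`, `sd`, `n` (one row per
#'   group, each `n >= 2`, each `sd >= 0`).
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
#' @examples
#' anova_from_summary(data.frame(mean = c(10.22, 11.6, 13.71),
#'                               sd = c(2.45, 2.07, 2.52),
#'                               n = c(12, 10, 17)))
anova_from_summary <- function(groups) {
  groups <- as.data.frame(groups)
  stopifnot(all(c("mean", "sd", "n") %in% names(groups)))
  if (nrow(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(groups$n < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(groups$sd < 0) || any(!is.finite(groups$sd))) {
    stop("group SDs must be finite and non-negative", call. = FALSE)
  }
  k <- nrow(groups)
  N <- sum(groups$n)
  grand <- sum(groups$n * groups$mean) / N
  ssb <- sum(groups$n * (groups$mean - grand)^2)
  ssw <- sum((groups$n - 1) * groups$sd^2)
  df1 <- k - 1L
  df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  tibble::tibble(statistic = f, df1 = df1, df2 = as.integer(df2),
                 p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Cohen's d from two group summaries
#'
#' `(mean_a - mean_b) / s_pooled` with the usual pooled SD
#' `sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b Each a list / one-row data frame / named vector with
#'   entries `mean`, `sd`, `n` (`n >= 2`).
#' @return Cohen's d (signed, a minus b).
#' @export
#' @examples
#' cohens_d_from_summary(c(mean = 34.36, sd = 9.53, n = 39),
#'                       c(mean = 32.21, sd = 9.60, n = 39))
cohens_d_from_summary <- function(a, b) {
  a <- as.list(as.data.frame(as.list(a)))
  b <- as.list(as.data.frame(as.list(b)))
  stopifnot(all(c("mean", "sd", "n") %in% names(a)),
            all(c("mean", "sd", "n") %in% names(b)))
  if (a$n < 2 || b$n < 2) stop("each group needs n >= 2", call. = FALSE)
  pooled <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
  if (pooled == 0) stop("pooled SD is zero; effect size undefined", call. = FALSE)
  (a$mean - b$mean) / pooled
}

#' Two-sided p-value for a Pearson correlation
#'
#' From `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
#' freedom.
#'
#' @param r Sample correlation, `|r| < 1`.
#' @param n Sample size, `n >= 3`.
#' @return Two-sided p-value.
#' @export
#' @examples
#' corr_pvalue(0.27, 39)
corr_pvalue <- function(r, n) {
  if (!is.finite(r) || abs(r) >= 1) {
    stop("`r` must satisfy |r| < 1", call. = FALSE)
  }
  if (n < 3) stop("`n` must be at least 3", call. = FALSE)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' @export
tidy.region_results <- function(x, ...) {
  tibble::as_tibble(unclass(x)[seq_along(x)])
}

#' @export
glance.region_results <- function(x, ...) {
  tibble::tibble(analysis = attr(x, "analysis"),
                 n_subjects = attr(x, "n"),
                 n_dropped = attr(x, "n_dropped"),
                 n_regions = length(unique(x$region)),
                 min_p = min(x$p))
}

#' Plot per-region association results
#'
#' Volcano-style display: effect estimate against -log10 p, one facet
#' per model term.
#'
#' @param object A `region_results` tibble from [fit_region_models()].
#' @param alpha Reference significance level drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_results <- function(object, alpha = 0.05, ...) {
  dat <- tidy.region_results(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate,
                                    y = -log10(.data$p))) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "effect estimate (mm³ per predictor unit)",
                  y = expression(-log[10](p)))
}
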