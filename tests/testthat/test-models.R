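test_that("planted noise-free effects are recovered exactly", {
  cohort <- exact_cohort()
  ps <- as.numeric(cohort$group == "psychopathic")

  vols <- tibble::tibble(subject = cohort$subject, r1 = 500 - 5 * ps)
  fit <- fit_group_model(vols, cohort, "r1")
  expect_equal(fit$estimate, -5, tolerance = 1e-8)
  expect_lt(fit$p, 1e-12)
  expect_equal(fit$df_resid, nrow(cohort) - 6)  # intercept, group, 2 site, age, icv

  # pure covariate signal: no group effect at all
  vols2 <- tibble::tibble(subject = cohort$subject, r1 = 2 * cohort$icv)
  fit2 <- fit_group_model(vols2, cohort, "r1")
  expect_lt(abs(fit2$estimate), 1e-8)
  expect_lt(abs(fit2$percent_diff), 1e-8)

  # factor model: effect on f2 only, tested after adjustment for f1
  psych <- cohort[cohort$group == "psychopathic", ]
  vols3 <- tibble::tibble(subject = cohort$subject, r1 = 0)
  vols3$r1[match(psych$subject, vols3$subject)] <- 4000 - 3 * psych$pclr_f2
  ff <- fit_factor_model(vols3, cohort, "r1")
  expect_equal(nrow(ff), 2)
  expect_equal(ff$estimate[ff$term == "pclr_f2"], -3, tolerance = 1e-8)
  expect_lt(abs(ff$estimate[ff$term == "pclr_f1"]), 1e-8)
  expect_equal(unique(ff$df_resid), 39 - 7)  # 7-column design at 3 sites

  vols4 <- tibble::tibble(subject = cohort$subject, r1 = 0)
  vols4$r1[match(psych$subject, vols4$subject)] <-
    1000 + 2 * psych$pclr_total
  ft <- fit_total_model(vols4, cohort, "r1")
  expect_equal(ft$estimate, 2, tolerance = 1e-8)
})

test_that("degenerate designs raise singularity and data errors", {
  cohort <- exact_cohort()
  vols <- tibble::tibble(subject = cohort$subject, r1 = rnorm(nrow(cohort)))

  const_total <- cohort
  const_total$pclr_total[const_total$group == "psychopathic"] <- 25
  expect_error(fit_total_model(vols, const_total, "r1"),
               "collinear.*pclr_total")

  collinear <- cohort
  collinear$icv <- 2 * collinear$age
  expect_error(fit_group_model(vols, collinear, "r1"), "collinear")

  controls_only <- cohort[cohort$group == "control", ]
  expect_error(fit_factor_model(vols, controls_only, "r1"),
               "no psychopathic subjects")
  one_group <- cohort
  one_group$group <- "control"
  expect_error(fit_group_model(vols, one_group, "r1"),
               "both groups")

  tiny <- cohort[c(1:2, 13:14), ]  # 4 subjects, 4 design columns
  expect_error(fit_group_model(vols, tiny, "r1"), "insufficient data")
})

test_that("coefficients, t and p match the normal-equations oracle", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(20:60, 1)
    n_sites <- sample(2:3, 1)
    analysis <- sample(c("group", "factors", "total"), 1)
    cohort <- tibble::tibble(
      subject = sprintf("s%03d", 1:n),
      group = if (analysis == "group") {
        sample(rep(c("psychopathic", "control"), length.out = n))
      } else "psychopathic",
      site = as.character(sample(1:n_sites, n, replace = TRUE)),
      age = runif(n, 18, 60), icv = rnorm(n, 1600, 120),
      pclr_total = runif(n, 20, 40),
      pclr_f1 = runif(n, 5, 16), pclr_f2 = runif(n, 5, 18))
    if (length(unique(cohort$site)) < n_sites ||
        (analysis == "group" && length(unique(cohort$group)) < 2)) next
    vols <- tibble::tibble(subject = cohort$subject,
                           r1 = rnorm(n, 5000, 300))
    fit <- fit_region_models(vols, cohort, analysis)

    # rebuild the design explicitly for the oracle
    site <- relevel(factor(cohort$site),
                    ref = names(which.max(table(cohort$site))))
    base <- model.matrix(~ site + age + icv,
                         data.frame(site = site, age = cohort$age,
                                    icv = cohort$icv))
    X <- switch(analysis,
      group = cbind(base, g = as.numeric(cohort$group == "psychopathic")),
      factors = cbind(base, f1 = cohort$pclr_f1, f2 = cohort$pclr_f2),
      total = cbind(base, tot = cohort$pclr_total))
    orc <- ols_oracle(X, vols$r1)
    terms <- switch(analysis, group = c(g = "group_psychopathic"),
                    factors = c(f1 = "pclr_f1", f2 = "pclr_f2"),
                    total = c(tot = "pclr_total"))
    for (nm in names(terms)) {
      row <- fit[fit$term == terms[[nm]], ]
      expect_equal(row$estimate, unname(orc$beta[nm]), tolerance = 1e-8)
      expect_equal(row$t, unname(orc$t[nm]), tolerance = 1e-8)
      expect_equal(row$p, unname(orc$p[nm]), tolerance = 1e-8)
      expect_equal(row$df_resid, orc$df)
      if (analysis == "group") {
        expect_equal(sign(row$percent_diff), sign(row$estimate))
      }
    }
  }
})

test_that("inference on the term of interest is invariant to site coding", {
  cohort <- exact_cohort()
  set.seed(8)
  vols <- tibble::tibble(subject = cohort$subject,
                         r1 = rnorm(nrow(cohort), 5000, 200))
  relabel <- c("1" = "3", "2" = "2", "3" = "1")  # flips the reference site
  cohort2 <- cohort
  cohort2$site <- relabel[cohort$site]
  for (analysis in c("group", "factors", "total")) {
    a <- fit_region_models(vols, cohort, analysis)
    b <- fit_region_models(vols, cohort2, analysis)
    expect_equal(a$t, b$t, tolerance = 1e-10)
    expect_equal(a$p, b$p, tolerance = 1e-10)
  }
})

test_that("subjects with missing required covariates are dropped with a message", {
  cohort <- exact_cohort()
  cohort$age[c(2, 5)] <- NA
  vols <- tibble::tibble(subject = cohort$subject,
                         r1 = rnorm(nrow(cohort), 5000, 200))
  expect_message(fit <- fit_group_model(vols, cohort, "r1"),
                 "dropping 2")
  expect_equal(attr(fit, "n_dropped"), 2)
  expect_equal(attr(fit, "n"), nrow(cohort) - 2)
})

test_that("summary-moment ANOVA equals a full-data one-way ANOVA", {
  specs <- list(
    data.frame(mean = c(10.22, 11.6, 13.71), sd = c(2.45, 2.07, 2.52),
               n = c(12, 10, 17)),
    data.frame(mean = c(5, 5, 5), sd = c(1, 2, 3), n = c(4, 6, 8)),
    data.frame(mean = c(0, 10), sd = c(2, 2), n = c(30, 40)))
  for (g in specs) {
    out <- anova_from_summary(g)
    # raw data affinely constructed to match each group's moments exactly
    y <- unlist(mapply(vector_with_moments, g$n, g$mean, g$sd,
                       SIMPLIFY = FALSE))
    grp <- factor(rep(seq_len(nrow(g)), g$n))
    full <- oneway.test(y ~ grp, var.equal = TRUE)
    expect_equal(out$statistic, unname(full$statistic), tolerance = 1e-10)
    expect_equal(out$p.value, unname(full$p.value), tolerance = 1e-10)
    expect_equal(out$df1, unname(full$parameter[1]))
    expect_equal(out$df2, unname(full$parameter[2]))
  }
  # identical means across groups: no between-group variance
  flat <- anova_from_summary(data.frame(mean = c(3, 3), sd = c(1, 1),
                                        n = c(5, 5)))
  expect_equal(flat$statistic, 0)
  expect_error(anova_from_summary(data.frame(mean = 1, sd = 1, n = 5)),
               "at least 2")
  expect_error(anova_from_summary(data.frame(mean = c(1, 2), sd = c(-1, 1),
                                             n = c(5, 5))),
               "non-negative")
  expect_error(anova_from_summary(data.frame(mean = c(1, 2), sd = c(1, 1),
                                             n = c(1, 5))),
               "n >= 2")
})

test_that("Cohen's d from summaries behaves at its landmarks", {
  d <- cohens_d_from_summary(c(mean = 34.36, sd = 9.53, n = 39),
                             c(mean = 32.21, sd = 9.60, n = 39))
  expect_equal(d, 0.2248, tolerance = 1e-3)
  expect_equal(cohens_d_from_summary(c(mean = 5, sd = 2, n = 10),
                                     c(mean = 5, sd = 3, n = 12)), 0)
  # means one pooled SD apart give exactly 1
  expect_equal(cohens_d_from_summary(c(mean = 3, sd = 2, n = 9),
                                     c(mean = 1, sd = 2, n = 9)), 1)
  expect_error(cohens_d_from_summary(c(mean = 1, sd = 0, n = 5),
                                     c(mean = 2, sd = 0, n = 5)),
               "pooled SD")
})

test_that("correlation p-values match the t reference", {
  expect_lt(abs(corr_pvalue(0.27, 39) - 0.0963), 5e-4)
  expect_equal(corr_pvalue(0, 25), 1)
  expect_error(corr_pvalue(1, 10), "\\|r\\| < 1")
  expect_error(corr_pvalue(0.5, 2), "at least 3")
  # numeric quadrature of the t density as an independent oracle
  r <- 0.5; n <- 20
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  dens <- function(x) {
    df <- n - 2
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  p_quad <- 2 * integrate(dens, tval, Inf, rel.tol = 1e-10)$value
  expect_equal(corr_pvalue(r, n), p_quad, tolerance = 1e-6)
})

test_that("tidy and glance summarise region results", {
  study <- simulate_study(simulation_config(seed = 12), toy_hierarchy())
  res <- fit_region_models(study$volumes, study$cohort, "group")
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "region_results"))
  gl <- glance(res)
  expect_equal(gl$n_regions, 39)
  expect_equal(gl$analysis, "group")
  expect_s3_class(autoplot(res), "ggplot")
})
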