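#' Run the full regional association pipeline
#'
#' Orchestrates one analysis end to end: load (or accept in-memory)
#' volume table, cohort table and region hierarchy; fit the per-region
#' covariate-adjusted models; assemble the hypothesis tree; run the
#' hierarchical FDR procedure; and optionally write report TSVs plus a
#' run manifest.
#'
#' Defaults encode the study's choices: initial threshold `q0 = 0.05`;
#' aggregate-signal family p-values for the group comparison, Simes for
#' the PCL-R score regressions; strict level-wise threshold reduction.
#' For `analysis = "factors"` the hierarchical procedure runs separately
#' per factor (both factors come from the one joint model).
#'
#' @param analysis `"group"`, `"factors"` or `"total"`.
#' @param volumes Volume table tibble or path to a volume TSV.
#' @param cohort Cohort tibble or path to a cohort TSV.
#' @param hierarchy A [region_tree()] or path to a hierarchy JSON.
#' @param q0 Initial FDR threshold.
#' @param mode `"strict"` or `"relaxed"` (see [run_hierarchy()]).
#' @param family_method `"simes"`, `"aggregate"`, or `NULL` for the
#'   per-analysis default (aggregate for group, Simes otherwise).
#' @param out_dir Output directory for report TSVs and the run manifest;
#'   `NULL` to skip writing.
#' @return A `pipeline_run` list: `analysis`, `results` (the
#'   `region_results` tibble), `fdr` (named list of `hier_fdr`, one per
#'   tested term), `reports` (named list of report tibbles as written).
#' @export
#' @examples
#' study <- simulate_study(simulation_config(seed = 3), toy_hierarchy())
#' run <- run_pipeline("factors", study$volumes, study$cohort,
#'                     toy_hierarchy())
#' run$fdr$pclr_f2
run_pipeline <- function(analysis, volumes, cohort, hierarchy,
                         q0 = 0.05, mode = c("strict", "relaxed"),
                         family_method = NULL, out_dir = NULL) {
  if (!analysis %in% c("group", "factors", "total")) {
    stop("unknown analysis: ", analysis,
         " (expected group, factors or total)", call. = FALSE)
  }
  mode <- match.arg(mode)
  if (is.character(volumes)) volumes <- read_volume_table(volumes)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(hierarchy)) hierarchy <- read_hierarchy(hierarchy)
  stopifnot(inherits(hierarchy, "region_tree"))
  if (is.null(family_method)) {
    family_method <- if (analysis == "group") "aggregate" else "simes"
  }
  family_method <- match.arg(family_method, c("simes", "aggregate"))

  only_vol <- setdiff(volumes$subject, cohort$subject)
  only_coh <- setdiff(cohort$subject, volumes$subject)
  if (length(only_vol) > 0 || length(only_coh) > 0) {
    stop("subject mismatch between volume and cohort tables; ",
         "volume-only: [", paste(only_vol, collapse = ", "),
         "], cohort-only: [", paste(only_coh, collapse = ", "), "]",
         call. = FALSE)
  }
  regions <- hierarchy$nodes$name
  absent <- setdiff(regions, names(volumes))
  if (length(absent) > 0) {
    stop("volume table is missing tree region(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  results <- fit_region_models(volumes, cohort, analysis, regions = regions)
  elem <- elementary_regions(hierarchy)
  internal <- setdiff(regions, elem)

  fdr <- list()
  reports <- list()
  for (term in unique(results$term)) {
    res_t <- results[results$term == term, ]
    node_p <- stats::setNames(res_t$p, res_t$region)
    agg_p <- if (family_method == "aggregate") node_p[internal] else NULL
    st <- run_hierarchy(hierarchy, node_p[elem], q0 = q0, mode = mode,
                        family_method = family_method, aggregate_p = agg_p)
    fdr[[term]] <- st
    reports[[term]] <- assemble_report(res_t, st)
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (term in names(reports)) {
      readr::write_tsv(reports[[term]],
                       file.path(out_dir, paste0("report_", term, ".tsv")))
    }
    manifest <- list(
      analysis = analysis, q0 = q0, mode = mode,
      family_method = family_method,
      n_subjects = nrow(cohort),
      n_subjects_modelled = attr(results, "n"),
      n_subjects_dropped = attr(results, "n_dropped"),
      n_regions = length(regions),
      package_version = as.character(utils::packageVersion("morphofdr")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(analysis = analysis, results = results, fdr = fdr,
                 reports = reports),
            class = "pipeline_run")
}

assemble_report <- function(results, state) {
  rep <- state$report
  res <- tibble::as_tibble(unclass(results)[
    c("region", "estimate", "t", "percent_diff")])
  out <- dplyr::left_join(rep, res, by = "region")
  out$discovered <- as.integer(out$discovered)
  out$parent_discovered <- as.integer(out$parent_discovered)
  dplyr::arrange(out, .data$level, .data$region)
}

#' Write a hierarchical-testing report table
#'
#' TSV with one row per region: `region`, `level`, `p`, `family_method`,
#' `q_level`, `discovered` (0/1), `parent_discovered` (0/1, empty for
#' the root), `path_to_root` (semicolon-joined, region first), plus the
#' model columns `estimate`, `t`, `percent_diff`.  Rows are ordered by
#' level then name; writing is idempotent.
#'
#' @param results A `region_results` tibble restricted to one term (may
#'   be empty, giving a header-only file).
#' @param state A `hier_fdr` object from [run_hierarchy()].
#' @param path Output TSV path.
#' @return The report tibble, invisibly.
#' @export
write_report <- function(results, state, path) {
  if (is.null(results) || nrow(results) == 0) {
    empty <- tibble::tibble(region = character(0), level = integer(0),
                            p = numeric(0), family_method = character(0),
                            q_level = numeric(0), discovered = integer(0),
                            parent_discovered = integer(0),
                            path_to_root = character(0),
                            estimate = numeric(0), t = numeric(0),
                            percent_diff = numeric(0))
    readr::write_tsv(empty, path)
    return(invisible(empty))
  }
  if (length(unique(results$term)) > 1) {
    stop("`results` must be restricted to a single model term",
         call. = FALSE)
  }
  out <- assemble_report(results, state)
  readr::write_tsv(out, path)
  invisible(out)
}

#' Read a report written by [write_report()]
#' @param path Report TSV path.
#' @return A tibble.
#' @export
read_report <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    region = readr::col_character(),
    family_method = readr::col_character(),
    path_to_root = readr::col_character(),
    level = readr::col_integer(),
    discovered = readr::col_integer(),
    parent_discovered = readr::col_integer(),
    .default = readr::col_double()))
}

#' Recompute the published univariate summary checks
#'
#' From the reference cohort summaries ([cohort_reference_summaries()]),
#' reconstructs the univariate statistics a reader can verify from the
#' group-description table alone: one-way ANOVAs across sites for the
#' PCL-R factors and for ICV within each group, the pooled two-group
#' ANOVA for age, Cohen's d for age, and the p-value of the reported
#' inter-factor correlation (r = 0.27, n = 39).
#'
#' @return A tibble with columns `check`, `value`, `df1`, `df2`,
#'   `p.value`.
#' @export
summary_statistic_checks <- function() {
  ref <- cohort_reference_summaries()
  site_rows <- function(measure, group) {
    x <- ref[ref$measure == measure & ref$group == group &
               ref$site != "pooled", ]
    data.frame(mean = x$mean, sd = x$sd, n = x$n)
  }
  f_row <- function(check, groups) {
    a <- anova_from_summary(groups)
    tibble::tibble(check = check, value = a$statistic, df1 = a$df1,
                   df2 = a$df2, p.value = a$p.value)
  }
  age <- ref[ref$measure == "age" & ref$site == "pooled", ]
  d_age <- cohens_d_from_summary(
    age[age$group == "psychopathic", c("mean", "sd", "n")],
    age[age$group == "control", c("mean", "sd", "n")])
  dplyr::bind_rows(
    f_row("anova_pclr_f1_across_sites",
          site_rows("pclr_f1", "psychopathic")),
    f_row("anova_pclr_f2_across_sites",
          site_rows("pclr_f2", "psychopathic")),
    f_row("anova_icv_across_sites_psychopathic",
          site_rows("icv", "psychopathic")),
    f_row("anova_icv_across_sites_control",
          site_rows("icv", "control")),
    f_row("anova_age_between_groups",
          data.frame(mean = age$mean, sd = age$sd, n = age$n)),
    tibble::tibble(check = "cohens_d_age", value = d_age,
                   df1 = NA_integer_, df2 = NA_integer_,
                   p.value = NA_real_),
    tibble::tibble(check = "corr_f1_f2_pvalue",
                   value = corr_pvalue(0.27, 39),
                   df1 = NA_integer_, df2 = 37L, p.value = NA_real_))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> analysis =", x$analysis, "\n")
  for (term in names(x$fdr)) {
    cat("  term", term, "->", length(x$fdr[[term]]$discovered),
        "discoveries\n")
  }
  invisible(x)
}
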