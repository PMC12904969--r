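#' Error-rate and power experiments for the hierarchical procedure
#'
#' `null_fdp_experiment()` estimates the false discovery proportion of
#' the tree procedure under a complete null: replicate synthetic cohorts
#' of psychopathic subjects with independent region noise and no planted
#' effects are generated, the chosen score model is fitted per
#' elementary region, and [run_hierarchy()] is applied.  With no true
#' effects every discovery is false, so each replicate's FDP is
#' `V / max(R, 1)` with `V = R` the number of discovered regions.
#'
#' @param n_rep Number of replicate cohorts.
#' @param q0 Initial FDR threshold.
#' @param tree Region hierarchy (default [toy_hierarchy()]).
#' @param sites Site sizes as in [simulation_config()]; the default is
#'   the emulated design's 39 psychopathic subjects (12/10/17), controls
#'   omitted because the score models use only the psychopathic group.
#' @param term Model term whose p-values feed the tree (default the
#'   PCL-R factor-2 coefficient).
#' @param mode `"strict"` or `"relaxed"`.
#' @param seed Integer seed for the whole experiment.
#' @return A tibble with one row per replicate: `replicate`,
#'   `n_discoveries`, `fdp`.
#' @export
#' @examples
#' res <- null_fdp_experiment(n_rep = 50, seed = 1)
#' mean(res$fdp)
null_fdp_experiment <- function(n_rep = 2000, q0 = 0.05,
                                tree = toy_hierarchy(),
                                sites = list(c(12, 0), c(10, 0), c(17, 0)),
                                term = "pclr_f2", mode = "strict",
                                seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 2L, n_rep)
  leaves <- elementary_regions(tree)
  cfg <- simulation_config(sites = sites, region_corr = 0, seed = seed)
  n_disc <- integer(n_rep)
  for (i in seq_len(n_rep)) {
    st <- simulate_study(cfg, tree, seed = rep_seeds[[i]])
    fit <- fit_region_models(st$volumes, st$cohort, "factors",
                             regions = leaves)
    p <- stats::setNames(fit$p[fit$term == term],
                         fit$region[fit$term == term])
    hr <- run_hierarchy(tree, p, q0 = q0, mode = mode,
                        family_method = "simes")
    n_disc[[i]] <- length(hr$discovered)
  }
  tibble::tibble(replicate = seq_len(n_rep), n_discoveries = n_disc,
                 fdp = ifelse(n_disc > 0, 1, 0))
}

#' @rdname null_fdp_experiment
#'
#' @details
#' `recovery_experiment()` plants a factor-2 volume effect on every
#' elementary region below `region` and measures how often the strict
#' hierarchical procedure discovers `region` itself.  The effect size is
#' calibrated, not hand-picked: a pilot set of simulated cohorts
#' supplies the sampling distribution of the factor-2 coefficient's
#' standard error, the noncentrality needed for the requested per-leaf
#' power at level `alpha` comes from the noncentral t distribution at
#' the design's residual degrees of freedom, and the planted `beta` is
#' their product.
#'
#' @param region Subtree root carrying the planted effect.
#' @param target_power Per-leaf power of the uncorrected two-sided test
#'   at level `alpha` that the planted effect is calibrated to.
#' @param alpha Level used in the power calibration.
#' @param n_calibration Number of pilot cohorts for the SE estimate.
#' @return For `recovery_experiment()`: a list with `beta` (planted
#'   effect, mm^3 per factor-2 point), `delta` (calibrated
#'   noncentrality), `df` (residual df of the design), `results` (tibble
#'   with `replicate`, `recovered`, `n_discoveries`, `connected`), and
#'   `recovery_rate`.
#' @export
recovery_experiment <- function(n_rep = 500, region = "left-frontal-lobe",
                                target_power = 0.9, alpha = 0.05,
                                q0 = 0.05, tree = toy_hierarchy(),
                                sites = list(c(12, 0), c(10, 0), c(17, 0)),
                                n_calibration = 100, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  cal_seeds <- sample.int(.Machine$integer.max - 2L, n_calibration)
  rep_seeds <- sample.int(.Machine$integer.max - 2L, n_rep)
  base_cfg <- simulation_config(sites = sites, region_corr = 0, seed = seed)

  # pilot: unit standard error of the factor-2 coefficient per cohort
  se_unit <- numeric(n_calibration)
  df_resid <- NA_integer_
  for (i in seq_len(n_calibration)) {
    coh <- simulate_cohort(base_cfg, seed = cal_seeds[[i]])
    des <- build_design(coh, "factors")
    xtx_inv <- solve(crossprod(des$X))
    se_unit[[i]] <- sqrt(xtx_inv["pclr_f2", "pclr_f2"])
    df_resid <- nrow(des$X) - ncol(des$X)
  }
  crit <- stats::qt(1 - alpha / 2, df_resid)
  power_at <- function(delta) {
    stats::pt(crit, df_resid, ncp = delta, lower.tail = FALSE) +
      stats::pt(-crit, df_resid, ncp = delta)
  }
  delta <- stats::uniroot(function(d) power_at(d) - target_power,
                          c(0, 20))$root
  beta <- delta * base_cfg$noise_sd * stats::median(se_unit)

  cfg <- simulation_config(
    sites = sites, region_corr = 0,
    effect_spec = data.frame(region = region, term = "f2", beta = -beta),
    seed = seed)
  leaves <- elementary_regions(tree)
  recovered <- logical(n_rep)
  n_disc <- integer(n_rep)
  connected <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    st <- simulate_study(cfg, tree, seed = rep_seeds[[i]])
    fit <- fit_region_models(st$volumes, st$cohort, "factors",
                             regions = leaves)
    p <- stats::setNames(fit$p[fit$term == "pclr_f2"],
                         fit$region[fit$term == "pclr_f2"])
    hr <- run_hierarchy(tree, p, q0 = q0, mode = "strict",
                        family_method = "simes")
    recovered[[i]] <- region %in% hr$discovered
    n_disc[[i]] <- length(hr$discovered)
    rep_tab <- hr$report
    connected[[i]] <- all(rep_tab$parent_discovered[rep_tab$discovered &
                                                      rep_tab$level > 0])
  }
  list(beta = beta, delta = delta, df = df_resid,
       results = tibble::tibble(replicate = seq_len(n_rep),
                                recovered = recovered,
                                n_discoveries = n_disc,
                                connected = connected),
       recovery_rate = mean(recovered))
}
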