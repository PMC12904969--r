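#' Reference summary statistics of the emulated cohort
#'
#' Per-site and pooled summary statistics (mean, SD, n) of the three-site
#' forensic study design that the simulator's defaults mirror: matched
#' psychopathic / control groups of sizes (12,12), (10,10), (17,17),
#' ages, intracranial volumes (cm^3) and PCL-R scores (assessed in the
#' psychopathic group only).  These are the published group descriptions
#' used as simulation targets and as inputs to the summary-statistic
#' utilities ([anova_from_summary()], [cohens_d_from_summary()]).
#'
#' @return A tibble with columns `measure`, `site` (`"1"`, `"2"`, `"3"`
#'   or `"pooled"`), `group`, `mean`, `sd`, `n`.
#' @export
cohort_reference_summaries <- function() {
  row <- function(measure, site, group, mean, sd, n)
    tibble::tibble(measure = measure, site = site, group = group,
                   mean = mean, sd = sd, n = n)
  dplyr::bind_rows(
    row("age", "1", "control", 37.42, 11.70, 12),
    row("age", "1", "psychopathic", 37.00, 11.00, 12),
    row("age", "2", "control", 28.90, 7.98, 10),
    row("age", "2", "psychopathic", 30.00, 7.53, 10),
    row("age", "3", "control", 30.47, 7.63, 17),
    row("age", "3", "psychopathic", 35.06, 9.11, 17),
    row("age", "pooled", "control", 32.21, 9.60, 39),
    row("age", "pooled", "psychopathic", 34.36, 9.53, 39),
    row("pclr_total", "1", "psychopathic", 23.02, 2.14, 12),
    row("pclr_total", "2", "psychopathic", 27.70, 4.62, 10),
    row("pclr_total", "3", "psychopathic", 33.29, 4.44, 17),
    row("pclr_total", "pooled", "psychopathic", 28.70, 5.88, 39),
    row("pclr_f1", "1", "psychopathic", 10.22, 2.45, 12),
    row("pclr_f1", "2", "psychopathic", 11.60, 2.07, 10),
    row("pclr_f1", "3", "psychopathic", 13.71, 2.52, 17),
    row("pclr_f1", "pooled", "psychopathic", 12.09, 2.79, 39),
    row("pclr_f2", "1", "psychopathic", 11.18, 2.55, 12),
    row("pclr_f2", "2", "psychopathic", 13.00, 1.94, 10),
    row("pclr_f2", "3", "psychopathic", 15.00, 2.09, 17),
    row("pclr_f2", "pooled", "psychopathic", 13.31, 2.71, 39),
    row("icv", "1", "control", 1641, 145, 12),
    row("icv", "1", "psychopathic", 1608, 131, 12),
    row("icv", "2", "control", 1605, 92, 10),
    row("icv", "2", "psychopathic", 1498, 56, 10),
    row("icv", "3", "control", 1648, 143, 17),
    row("icv", "3", "psychopathic", 1582, 99, 17)
  )
}

#' Simulation configuration
#'
#' Defines the study conditions the synthetic generator emulates: a
#' multi-site case-control cohort with PCL-R scores in the case group,
#' and region volumes that scale with head size (ICV), shift by site,
#' drift with age, and carry plantable group / score effects on subtrees
#' of the region hierarchy.
#'
#' Defaults mirror the three-site design in
#' [cohort_reference_summaries()]: sites (12,12), (10,10), (17,17)
#' (psychopathic, control); age ~ N(33, 9.5^2) years clipped to the
#' study's 18-60 inclusion range; ICV ~ N(1600, 120^2) cm^3 clipped at
#' 4 SD; PCL-R factors bivariate normal with correlation 0.27, per-site
#' means/SDs from the reference table, clipped to the instrument ranges
#' (factor 1: 0-16, factor 2: 0-18, total: 20-40) and rounded to the
#' integer score grid.
#'
#' @param sites List of `c(n_psychopathic, n_control)` pairs, one per
#'   site.
#' @param age_mean,age_sd Age distribution (years).
#' @param icv_mean,icv_sd Intracranial volume distribution (cm^3).
#' @param factor_corr Target correlation between PCL-R factors 1 and 2.
#' @param effect_spec Planted effects: a data frame with columns
#'   `region` (a tree node; the effect is planted on every elementary
#'   descendant), `term` (`"group"`, `"f1"`, `"f2"`, `"total"`) and
#'   `beta` (mm^3 per predictor unit; for `"group"`, the mm^3 shift in
#'   psychopathic subjects).  `NULL` for no effects.
#' @param noise_sd Residual volume SD per region (mm^3).
#' @param region_corr Exchangeable residual correlation across regions,
#'   in \[0, 1).
#' @param site_shift Per-site volume shift as a fraction of each
#'   region's baseline volume.
#' @param age_slope_pct Volume change per year of age as a fraction of
#'   baseline (e.g. -0.002 = -0.2\%/year).
#' @param pclr_by_site Optional data frame (one row per site) with
#'   columns `f1_mean`, `f1_sd`, `f2_mean`, `f2_sd`, `total_mean`,
#'   `total_sd` overriding the reference PCL-R distributions.
#' @param baseline Optional named vector of baseline volumes (mm^3) for
#'   the elementary regions; defaults to a deterministic ramp over
#'   2000-10000 mm^3.
#' @param seed Integer seed; mandatory, used (with fixed offsets per
#'   generator) by every stochastic call.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(sites = list(c(12, 12), c(10, 10), c(17, 17)),
                              age_mean = 33, age_sd = 9.5,
                              icv_mean = 1600, icv_sd = 120,
                              factor_corr = 0.27,
                              effect_spec = NULL,
                              noise_sd = 150,
                              region_corr = 0,
                              site_shift = c(0, -0.01, 0.01),
                              age_slope_pct = -0.002,
                              pclr_by_site = NULL,
                              baseline = NULL,
                              seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("`seed` is mandatory", call. = FALSE)
  }
  ns <- unlist(sites)
  if (any(ns < 0)) stop("site sizes must be non-negative", call. = FALSE)
  if (age_sd < 0 || icv_sd < 0) stop("SDs must be non-negative", call. = FALSE)
  if (!is.finite(factor_corr) || abs(factor_corr) >= 1) {
    stop("|factor_corr| must be < 1", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (region_corr < 0 || region_corr >= 1) {
    stop("`region_corr` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(effect_spec)) {
    effect_spec <- tibble::as_tibble(effect_spec)
    stopifnot(all(c("region", "term", "beta") %in% names(effect_spec)))
    if (!all(effect_spec$term %in% c("group", "f1", "f2", "total"))) {
      stop("effect terms must be group/f1/f2/total", call. = FALSE)
    }
  }
  S <- length(sites)
  if (is.null(pclr_by_site)) {
    if (S == 3) {
      pclr_by_site <- data.frame(
        f1_mean = c(10.22, 11.60, 13.71), f1_sd = c(2.45, 2.07, 2.52),
        f2_mean = c(11.18, 13.00, 15.00), f2_sd = c(2.55, 1.94, 2.09),
        total_mean = c(23.02, 27.70, 33.29), total_sd = c(2.14, 4.62, 4.44))
    } else {
      pclr_by_site <- data.frame(
        f1_mean = rep(12.09, S), f1_sd = rep(2.79, S),
        f2_mean = rep(13.31, S), f2_sd = rep(2.71, S),
        total_mean = rep(28.70, S), total_sd = rep(5.88, S))
    }
  }
  if (nrow(pclr_by_site) != S) {
    stop("`pclr_by_site` needs one row per site", call. = FALSE)
  }
  site_shift <- rep_len(site_shift, S)
  structure(list(sites = sites, age_mean = age_mean, age_sd = age_sd,
                 icv_mean = icv_mean, icv_sd = icv_sd,
                 factor_corr = factor_corr, effect_spec = effect_spec,
                 noise_sd = noise_sd, region_corr = region_corr,
                 site_shift = site_shift, age_slope_pct = age_slope_pct,
                 pclr_by_site = tibble::as_tibble(pclr_by_site),
                 baseline = baseline, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Read / write a simulation configuration (YAML)
#' @param path File path.
#' @return A [simulation_config()] (read) or `path` invisibly (write).
#' @export
read_simulation_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$sites)) x$sites <- lapply(x$sites, unlist)
  if (!is.null(x$effect_spec)) {
    x$effect_spec <- dplyr::bind_rows(lapply(x$effect_spec, tibble::as_tibble))
  }
  if (!is.null(x$pclr_by_site)) {
    x$pclr_by_site <- dplyr::bind_rows(lapply(x$pclr_by_site, tibble::as_tibble))
  }
  if (!is.null(x$baseline)) x$baseline <- unlist(x$baseline)
  do.call(simulation_config, x)
}

#' @rdname read_simulation_config
#' @param config A [simulation_config()].
#' @export
write_simulation_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$effect_spec)) x$effect_spec <- as.data.frame(x$effect_spec)
  if (!is.null(x$pclr_by_site)) x$pclr_by_site <- as.data.frame(x$pclr_by_site)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Simulate a multi-site case-control cohort
#'
#' Draws subjects per site and group with ages and ICVs from the
#' configured (clipped) normal distributions and, for psychopathic
#' subjects, PCL-R factor scores from a bivariate normal with the
#' configured inter-factor correlation, clipped to the instrument ranges
#' and rounded to the integer score grid; totals are floored at the
#' study's inclusion cutoff of 20.  Controls carry no PCL-R scores.
#'
#' @param config A [simulation_config()].
#' @param seed Seed for this call (default: the config's seed).
#' @return A cohort tibble (see [read_cohort()]).
#' @export
#' @examples
#' simulate_cohort(simulation_config(seed = 7))
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  rows <- list()
  idx <- 0
  for (s in seq_along(config$sites)) {
    for (g in c("psychopathic", "control")) {
      n <- config$sites[[s]][[if (g == "psychopathic") 1 else 2]]
      if (n == 0) next
      age <- pmin(pmax(stats::rnorm(n, config$age_mean, config$age_sd),
                       18), 60)
      icv <- pmin(pmax(stats::rnorm(n, config$icv_mean, config$icv_sd),
                       config$icv_mean - 4 * config$icv_sd),
                  config$icv_mean + 4 * config$icv_sd)
      if (g == "psychopathic") {
        ps <- config$pclr_by_site[s, ]
        rho <- config$factor_corr
        z1 <- stats::rnorm(n)
        z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
        f1 <- round(pmin(pmax(ps$f1_mean + ps$f1_sd * z1, 0), 16))
        f2 <- round(pmin(pmax(ps$f2_mean + ps$f2_sd * z2, 0), 18))
        total <- round(pmin(pmax(
          stats::rnorm(n, ps$total_mean, ps$total_sd), 20), 40))
      } else {
        f1 <- f2 <- total <- rep(NA_real_, n)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = sprintf("s%03d", idx + seq_len(n)),
        group = g, site = as.character(s), age = age, icv = icv,
        pclr_total = total, pclr_f1 = f1, pclr_f2 = f2)
      idx <- idx + n
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(subject = character(0), group = character(0),
                          site = character(0), age = numeric(0),
                          icv = numeric(0), pclr_total = numeric(0),
                          pclr_f1 = numeric(0), pclr_f2 = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

default_baselines <- function(tree) {
  leaves <- elementary_regions(tree)
  stats::setNames(round(seq(2000, 10000, length.out = length(leaves))),
                  leaves)
}

#' Simulate region volumes for a cohort
#'
#' Each elementary region volume follows the structure the per-region
#' models assume:
#' `baseline * (icv / icv_mean)` (head-size scaling) `+` a per-site
#' shift `+` an age drift `+` planted effects times their predictor `+`
#' exchangeably correlated Gaussian noise.  Score predictors (f1, f2,
#' total) are centred within the psychopathic group and contribute zero
#' for controls, so a planted `beta` is recovered as the corresponding
#' regression coefficient.  Superordinate volumes are child sums via
#' [aggregate_volumes()].
#'
#' @param config A [simulation_config()].
#' @param cohort A cohort tibble (e.g. from [simulate_cohort()]).
#' @param tree A [region_tree()].
#' @param seed Seed for this call (default: config seed + 1, a stream
#'   offset distinct from [simulate_cohort()]).
#' @return A `simulated_study` list: `cohort`, `volumes` (full volume
#'   table over all tree nodes), `truth` (tibble `region`, `term`,
#'   `beta` covering the named regions and all their descendants).
#' @export
simulate_volumes <- function(config, cohort, tree,
                             seed = config$seed + 1L) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(tree, "region_tree"))
  set.seed(seed)
  cohort <- tibble::as_tibble(cohort)
  leaves <- elementary_regions(tree)
  baseline <- config$baseline
  if (is.null(baseline)) baseline <- default_baselines(tree)
  absent <- setdiff(leaves, names(baseline))
  if (length(absent) > 0) {
    stop("baseline volumes missing for region(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- nrow(cohort)
  L <- length(leaves)
  site_i <- as.integer(factor(cohort$site,
                              levels = as.character(seq_along(config$sites))))

  predictor <- function(term) {
    if (term == "group") return(as.numeric(cohort$group == "psychopathic"))
    col <- switch(term, f1 = "pclr_f1", f2 = "pclr_f2", total = "pclr_total")
    x <- cohort[[col]]
    ps <- !is.na(x)
    out <- numeric(n)
    out[ps] <- x[ps] - mean(x[ps])
    out
  }

  # leaf-level planted effects: named region's elementary descendants
  eff <- matrix(0, n, L, dimnames = list(NULL, leaves))
  truth <- tibble::tibble(region = character(0), term = character(0),
                          beta = numeric(0))
  if (!is.null(config$effect_spec)) {
    for (i in seq_len(nrow(config$effect_spec))) {
      spec <- config$effect_spec[i, ]
      if (!spec$region %in% tree$nodes$name) {
        stop("effect_spec names unknown region: ", spec$region,
             call. = FALSE)
      }
      target_leaves <- elementary_descendants(tree, spec$region)
      x <- predictor(spec$term)
      for (r in target_leaves) eff[, r] <- eff[, r] + spec$beta * x
      # every node in the planted subtree carries a truth record; an
      # internal node's effective beta is the sum over its leaves
      sub <- subtree_nodes(tree, spec$region)
      betas <- vapply(sub, function(nd) {
        spec$beta * length(intersect(elementary_descendants(tree, nd),
                                     target_leaves))
      }, numeric(1))
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        region = sub, term = spec$term, beta = betas))
    }
    truth <- dplyr::summarise(dplyr::group_by(truth, .data$region,
                                              .data$term),
                              beta = sum(.data$beta), .groups = "drop")
  }

  rho <- config$region_corr
  z0 <- stats::rnorm(n)
  zr <- matrix(stats::rnorm(n * L), n, L)
  noise <- config$noise_sd * (sqrt(rho) * z0 + sqrt(1 - rho) * zr)

  bl <- baseline[leaves]
  vol <- outer(cohort$icv / config$icv_mean, bl) +
    outer(config$site_shift[site_i], bl) +
    outer(config$age_slope_pct * (cohort$age - config$age_mean), bl) +
    eff + noise
  elem <- tibble::as_tibble(as.data.frame(vol))
  elem <- dplyr::bind_cols(tibble::tibble(subject = cohort$subject), elem)
  volumes <- aggregate_volumes(tree, elem)
  structure(list(cohort = cohort, volumes = volumes, truth = truth,
                 config = config),
            class = "simulated_study")
}

# all nodes of the subtree rooted at `region`, including itself
subtree_nodes <- function(tree, region) {
  acc <- character(0)
  stack <- region
  while (length(stack) > 0) {
    cur <- stack[[1]]
    stack <- stack[-1]
    acc <- c(acc, cur)
    stack <- c(stack, family_of(tree, cur))
  }
  acc
}

#' Simulate a full synthetic study (cohort + volumes)
#'
#' @inheritParams simulate_volumes
#' @return A `simulated_study` (see [simulate_volumes()]).
#' @export
simulate_study <- function(config, tree, seed = config$seed) {
  cohort <- simulate_cohort(config, seed = seed)
  simulate_volumes(config, cohort, tree, seed = seed + 1L)
}

#' Simulate voxel maps exercising the volumetry path
#'
#' Lays the tree's elementary regions out as disjoint blocky
#' probabilistic maps on a small grid (full membership in the block
#' core, probability 0.5 on the one-voxel boundary shell) and builds one
#' LVR map per subject that equals the region's atrophy factor inside
#' each region and 1 elsewhere, plus optional Gaussian noise (clipped at
#' zero).
#'
#' @param config A [simulation_config()] (supplies subjects and the
#'   seed).
#' @param tree A [region_tree()].
#' @param atrophy Named vector of positive per-region LVR scale factors
#'   (default 1 everywhere).
#' @param dim Edge length of the cubic grid (<= 32).
#' @param voxel_size Voxel edge length in mm.
#' @param lvr_noise_sd SD of voxel-wise LVR noise.
#' @param seed Seed (default: config seed + 2).
#' @return List with `lvr_maps` (named by subject), `prob_maps` (named
#'   by region) and `reference` (tibble of per-region reference volumes,
#'   `sum(p) * voxel_volume`).
#' @export
simulate_lvr_maps <- function(config, tree, atrophy = NULL, dim = 24,
                              voxel_size = 2, lvr_noise_sd = 0,
                              seed = config$seed + 2L) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(tree, "region_tree"))
  if (dim > 32) stop("`dim` must be <= 32", call. = FALSE)
  set.seed(seed)
  leaves <- elementary_regions(tree)
  if (is.null(atrophy)) {
    atrophy <- stats::setNames(rep(1, length(leaves)), leaves)
  }
  if (any(atrophy <= 0)) stop("atrophy factors must be > 0", call. = FALSE)
  absent <- setdiff(leaves, names(atrophy))
  if (length(absent) > 0) {
    stop("atrophy factors missing for region(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  cell <- 5L  # 4^3 block + 1 voxel spacing keeps blocks disjoint
  m <- floor(dim / cell)
  if (length(leaves) > m^3) {
    stop("grid of dim ", dim, " cannot hold ", length(leaves),
         " disjoint region blocks", call. = FALSE)
  }
  vv <- voxel_size^3
  prob_maps <- list()
  for (i in seq_along(leaves)) {
    g <- array(0, c(dim, dim, dim))
    pos <- c((i - 1) %% m, ((i - 1) %/% m) %% m, (i - 1) %/% m^2)
    o <- pos * cell
    g[o[1] + 1:4, o[2] + 1:4, o[3] + 1:4] <- 0.5
    g[o[1] + 2:3, o[2] + 2:3, o[3] + 2:3] <- 1
    prob_maps[[leaves[i]]] <- prob_map(g, region = leaves[i])
  }
  n_subj <- sum(unlist(config$sites))
  subjects <- sprintf("s%03d", seq_len(n_subj))
  lvr_maps <- list()
  for (s in subjects) {
    g <- array(1, c(dim, dim, dim))
    for (r in leaves) {
      inside <- prob_maps[[r]]$grid > 0
      g[inside] <- atrophy[[r]]
    }
    if (lvr_noise_sd > 0) {
      g <- pmax(g + array(stats::rnorm(dim^3, 0, lvr_noise_sd),
                          c(dim, dim, dim)), 0)
    }
    lvr_maps[[s]] <- lvr_map(g, voxel_volume = vv, subject = s)
  }
  reference <- tibble::tibble(
    region = leaves,
    volume = vapply(leaves, function(r) vv * sum(prob_maps[[r]]$grid),
                    numeric(1), USE.NAMES = FALSE))
  list(lvr_maps = lvr_maps, prob_maps = prob_maps, reference = reference)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("<simulated_study> ", nrow(x$cohort), " subjects, ",
      ncol(x$volumes) - 1, " regions, ",
      nrow(x$truth), " planted-effect record(s)\n", sep = "")
  invisible(x)
}
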