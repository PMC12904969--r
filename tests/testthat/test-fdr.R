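test_that("Simes family p-value matches its defining formula", {
  expect_equal(simes_pvalue(0.2), 0.2)
  expect_equal(simes_pvalue(c(0.01, 0.04, 0.9)), 0.03)
  expect_equal(simes_pvalue(c(1, 1, 1)), 1)
  expect_error(simes_pvalue(numeric(0)), "non-empty")
  expect_error(simes_pvalue(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Simes p is bounded, monotone and permutation-invariant", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:10, 1)
    p <- runif(n)
    s <- simes_pvalue(p)
    expect_gte(s, min(p))
    expect_lte(s, min(1, n * min(p)))
    expect_equal(simes_pvalue(sample(p)), s)
    # monotone non-decreasing in every component
    j <- sample(n, 1)
    p_up <- p
    p_up[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_gte(simes_pvalue(p_up), s)
  }
})

test_that("Simes is exact for independent uniform p-values", {
  set.seed(2024)
  reps <- 50000
  pm <- matrix(runif(reps * 5), ncol = 5)
  sp <- apply(pm, 1, simes_pvalue)
  for (alpha in c(0.01, 0.05, 0.2)) {
    mc_se <- sqrt(alpha * (1 - alpha) / reps)
    expect_lt(abs(mean(sp <= alpha) - alpha), 3 * mc_se)
  }
})

test_that("within-family BH equals the step-up definition and p.adjust", {
  expect_equal(bh_within_family(rep(1, 4), 0.05), integer(0))
  expect_setequal(bh_within_family(c(0.01, 0.02, 0.04, 0.9), 0.05), 1:2)
  expect_equal(bh_within_family(0.04, 0.05), 1L)
  expect_error(bh_within_family(c(0.1), 1.5), "\\[0, 1\\]")
  expect_error(bh_within_family(c(0.1, 2), 0.05), "\\[0, 1\\]")

  set.seed(7)
  grid <- c(0.001, 0.009, 0.01, 0.02, 0.049, 0.05, 0.2, 0.5, 1)
  for (i in 1:300) {
    n <- sample(1:6, 1)
    p <- if (i %% 2 == 0) sample(grid, n, replace = TRUE) else runif(n)
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    got <- bh_within_family(p, q)
    expect_setequal(got, bh_oracle(p, q))
    expect_setequal(got, which(p.adjust(p, "BH") <= q))
  }
})

test_that("aggregate family p-values equal direct fits of the summed signal", {
  tr <- toy_hierarchy()
  study <- simulate_study(simulation_config(seed = 31), tr)

  # singleton family: identical to the child's own model p
  mini <- region_tree(data.frame(name = c("p", "a"), parent = c(NA, "p")))
  vols <- tibble::tibble(subject = study$cohort$subject,
                         a = study$volumes$pons, p = study$volumes$pons)
  agg <- family_pvalue_aggregate(vols, study$cohort, mini, "p", "total")
  direct <- fit_total_model(vols, study$cohort, "a")
  expect_equal(agg$p, direct$p, tolerance = 1e-12)

  # exactly opposite planted factor-2 effects cancel in the family sum
  cohort <- study$cohort
  psych <- cohort$group == "psychopathic"
  f2 <- ifelse(psych, cohort$pclr_f2, 0)
  duo <- region_tree(data.frame(name = c("p", "a", "b"),
                                parent = c(NA, "p", "p")))
  vols2 <- tibble::tibble(subject = cohort$subject,
                          a = 3000 + 5 * f2, b = 3000 - 5 * f2)
  agg2 <- family_pvalue_aggregate(vols2, cohort, duo, "p", "factors")
  expect_lt(abs(agg2$estimate[agg2$term == "pclr_f2"]), 1e-8)

  # fixture family: p equals directly fitting the pre-summed column
  kids <- family_of(tr, "mesencephalon")
  pre <- tibble::tibble(
    subject = study$volumes$subject,
    mesencephalon = rowSums(as.matrix(study$volumes[, kids])))
  agg3 <- family_pvalue_aggregate(study$volumes, study$cohort, tr,
                                  "mesencephalon", "group")
  direct3 <- fit_group_model(pre, study$cohort, "mesencephalon")
  expect_equal(agg3$p, direct3$p, tolerance = 1e-12)
})

test_that("hierarchical testing follows the hand-worked traversal", {
  # three-level tree: root over three branches, one with two leaves
  tr <- region_tree(data.frame(
    name = c("root", "a", "b", "c", "a1", "a2"),
    parent = c(NA, "root", "root", "root", "a", "a")))
  p <- c(a1 = 0.0005, a2 = 0.0012, b = 0.2, c = 0.9)
  # family p for a = min(2*0.0005, 0.0012) = 0.001; root Simes over
  # (0.001, 0.2, 0.9) = 0.003 -> gate open; BH on {a,b,c} at 0.05
  # rejects only a (0.001 <= 0.05/3); next-level threshold 0.05 * 1/3
  st <- run_hierarchy(tr, p, q0 = 0.05, mode = "strict")
  rep <- st$report
  expect_equal(rep$p[rep$region == "a"], 0.001)
  expect_equal(rep$p[rep$region == "root"], 0.003)
  expect_setequal(st$discovered, c("root", "a", "a1", "a2"))
  expect_equal(rep$q_level[rep$region == "b"], 0.05)
  expect_equal(rep$q_level[rep$region == "a1"], 0.05 / 3)
  expect_equal(rep$q_level[rep$region == "a2"], 0.05 / 3)

  # closed gate at the root blocks everything
  st2 <- run_hierarchy(tr, c(a1 = 0.9, a2 = 0.95, b = 0.9, c = 0.97),
                       q0 = 0.05)
  expect_length(st2$discovered, 0)
  expect_true(all(is.na(st2$report$q_level[st2$report$region != "root"])))

  # a tiny p under an undiscovered parent is never discovered
  p3 <- c(a1 = 0.001, a2 = 0.9, b = 0.0004, c = 0.0005)
  # force an undiscovered parent over a tiny child p via aggregate mode
  agg <- c(root = 0.01, a = 0.5)
  st4 <- run_hierarchy(tr, p3, q0 = 0.05, family_method = "aggregate",
                       aggregate_p = agg)
  expect_false("a" %in% st4$discovered)
  expect_false("a1" %in% st4$discovered)  # p = 0.001, parent closed

  expect_error(run_hierarchy(tr, p[1:2]), "missing p-value")
  expect_error(run_hierarchy(tr, p, q0 = 0), "\\(0, 1\\]")
  expect_error(run_hierarchy(tr, p, family_method = "aggregate",
                             aggregate_p = c(root = 0.01)),
               "aggregate family p-value")
})

test_that("strict discoveries form a root-connected subtree with shrinking thresholds", {
  tr <- toy_hierarchy()
  leaves <- elementary_regions(tr)
  parent_of <- setNames(tr$nodes$parent, tr$nodes$name)
  set.seed(99)
  for (i in 1:50) {
    p <- setNames(runif(length(leaves))^sample(1:4, 1), leaves)
    strict <- run_hierarchy(tr, p, q0 = 0.1, mode = "strict")
    relaxed <- run_hierarchy(tr, p, q0 = 0.1, mode = "relaxed")
    for (r in strict$discovered) {
      pa <- parent_of[[r]]
      if (!is.na(pa)) expect_true(pa %in% strict$discovered)
    }
    # relaxed-mode discoveries contain the strict-mode set
    expect_true(all(strict$discovered %in% relaxed$discovered))
    # thresholds never grow along any root path
    rep <- strict$report
    q_of <- setNames(rep$q_level, rep$region)
    for (r in leaves) {
      qs <- q_of[path_to_root(tr, r)]
      qs <- rev(qs[!is.na(qs)])
      if (length(qs) > 1) expect_true(all(diff(qs) <= 1e-12))
    }
  }
})
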