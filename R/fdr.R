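#' Simes combined p-value for a family of hypotheses
#'
#' For a family of N member p-values sorted increasingly,
#' `p_Simes = min_j p_(j) * N / j`.  Exact under independence,
#' permutation-invariant, and bounded between `p_(1)` and
#' `min(1, N * p_(1))`.
#'
#' @param pvals Non-empty numeric vector of p-values in \[0, 1\].
#' @return The Simes family p-value.
#' @export
#' @examples
#' simes_pvalue(c(0.01, 0.04, 0.9))  # 0.03
simes_pvalue <- function(pvals) {
  if (length(pvals) == 0) stop("`pvals` must be non-empty", call. = FALSE)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n <- length(pvals)
  min(1, min(sort(pvals) * n / seq_len(n)))
}

#' Benjamini-Hochberg step-up within one family
#'
#' Standard step-up rule at FDR threshold `q`: with sorted p-values
#' `p_(1) <= ... <= p_(N)`, find the largest k with
#' `p_(k) <= k * q / N` and reject every hypothesis with
#' `p <= p_(k)` (so boundary ties are rejected together).
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param q FDR threshold in \[0, 1\].
#' @return Integer indices (into `pvals`) of the rejected hypotheses;
#'   empty if none.
#' @export
#' @examples
#' bh_within_family(c(0.01, 0.02, 0.04, 0.9), 0.05)  # 1 2
bh_within_family <- function(pvals, q) {
  if (!is.numeric(q) || length(q) != 1 || !is.finite(q) || q < 0 || q > 1) {
    stop("`q` must be a single value in [0, 1]", call. = FALSE)
  }
  if (length(pvals) == 0) return(integer(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n <- length(pvals)
  ps <- sort(pvals)
  ok <- which(ps <= seq_len(n) * q / n)
  if (length(ok) == 0) return(integer(0))
  which(pvals <= ps[max(ok)])
}

#' Family p-value by aggregating the regional signal
#'
#' Instead of combining member p-values, sum the children's volumes per
#' subject into one synthetic region and test that directly with the
#' per-region model.  More sensitive than Simes for diffuse effects
#' spread over a whole family; less sensitive for strong focal effects.
#'
#' Because superordinate volumes are themselves child sums, this equals
#' fitting the parent's own volume column when the table was built with
#' [aggregate_volumes()].
#'
#' @inheritParams fit_region_models
#' @param tree A [region_tree()].
#' @param parent Parent region whose family (children) is aggregated;
#'   for an elementary region the region itself is tested.
#' @return A `region_results` tibble for the aggregated signal (one row
#'   per model term; for `analysis = "factors"` the caller selects the
#'   factor of interest).
#' @export
family_pvalue_aggregate <- function(volumes, cohort, tree, parent,
                                    analysis = c("group", "factors", "total")) {
  analysis <- match.arg(analysis)
  stopifnot(inherits(tree, "region_tree"))
  kids <- family_of(tree, parent)
  if (length(kids) == 0) kids <- parent
  absent <- setdiff(kids, names(volumes))
  if (length(absent) > 0) {
    stop("volume table is missing region(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  agg <- tibble::tibble(
    subject = volumes$subject,
    family = rowSums(as.matrix(tibble::as_tibble(volumes)[, kids, drop = FALSE])))
  names(agg)[2] <- parent
  fit_region_models(agg, cohort, analysis, regions = parent)
}

#' Hierarchical FDR over a region tree
#'
#' Tree-structured multiple testing: every internal node carries a family
#' p-value (Simes over its children's p-values, computed bottom-up, or an
#' externally supplied aggregate-signal p); testing proceeds top-down.
#' The root must itself pass (`p_root <= q0`) before any descent.  Within
#' each family of children of a discovered node, [bh_within_family()] is
#' applied; only children of discovered parents are ever considered.  In
#' `strict` mode the threshold shrinks along each path by the proportion
#' of discoveries in the parent's family,
#' `q_l = q_(l-1) * #discoveries / #children`,
#' so descent stops wherever a family yields no discoveries.  In
#' `relaxed` mode the threshold stays at `q0` on all levels but a
#' discovery still requires a fully-discovered path from the root.
#'
#' When a level mixes families with different parents, each family is
#' tested at the threshold propagated along its own path (path-local
#' thresholds), which reduces to the per-level rule on balanced
#' discovery patterns.
#'
#' @param tree A [region_tree()].
#' @param node_p P-values for the elementary regions: a named numeric
#'   vector or a data frame with columns `region`, `p`.  With
#'   `family_method = "aggregate"` it may (and for internal nodes must,
#'   via `aggregate_p`) cover internal regions too.
#' @param q0 Initial FDR threshold in (0, 1\] (default 0.05).
#' @param mode `"strict"` (level-wise threshold reduction) or
#'   `"relaxed"` (constant `q0` with the connected-path requirement).
#' @param family_method `"simes"` (internal p-values combined bottom-up
#'   from the children) or `"aggregate"` (internal p-values supplied in
#'   `aggregate_p`, from [family_pvalue_aggregate()] or equivalent).
#' @param aggregate_p Named vector / `region`,`p` data frame of p-values
#'   for every internal node; required for `family_method = "aggregate"`.
#' @return A `hier_fdr` object; its `report` tibble has one row per
#'   region with `region`, `level`, `p`, `family_method`, `q_level`
#'   (threshold at which the region's family was tested, `NA` if never
#'   reached), `discovered`, `parent_discovered`, `path_to_root`.
#' @export
#' @examples
#' tr <- toy_hierarchy()
#' p <- stats::setNames(runif(length(elementary_regions(tr))),
#'                      elementary_regions(tr))
#' run_hierarchy(tr, p)
run_hierarchy <- function(tree, node_p, q0 = 0.05,
                          mode = c("strict", "relaxed"),
                          family_method = c("simes", "aggregate"),
                          aggregate_p = NULL) {
  mode <- match.arg(mode)
  family_method <- match.arg(family_method)
  stopifnot(inherits(tree, "region_tree"))
  if (!is.numeric(q0) || length(q0) != 1 || !is.finite(q0) ||
      q0 <= 0 || q0 > 1) {
    stop("`q0` must be a single value in (0, 1]", call. = FALSE)
  }
  as_p_vec <- function(x) {
    if (is.data.frame(x)) x <- stats::setNames(x$p, x$region)
    x
  }
  node_p <- as_p_vec(node_p)
  aggregate_p <- as_p_vec(aggregate_p)

  nodes <- tree$nodes
  leaves <- nodes$name[nodes$is_elementary]
  internal <- nodes$name[!nodes$is_elementary]
  absent <- setdiff(leaves, names(node_p))
  if (length(absent) > 0) {
    stop("missing p-value(s) for elementary region(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  bad <- node_p[!is.na(node_p) & (node_p < 0 | node_p > 1)]
  if (length(bad) > 0) stop("p-values must lie in [0, 1]", call. = FALSE)

  p_all <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$name)
  p_all[leaves] <- node_p[leaves]
  if (family_method == "simes") {
    by_depth <- internal[order(nodes$level[match(internal, nodes$name)],
                               decreasing = TRUE)]
    for (r in by_depth) p_all[r] <- simes_pvalue(p_all[family_of(tree, r)])
  } else {
    src <- c(aggregate_p, node_p)
    absent <- setdiff(internal, names(src))
    if (length(absent) > 0) {
      stop("aggregate family p-value(s) missing for internal region(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    p_all[internal] <- src[internal]
  }

  discovered <- stats::setNames(rep(FALSE, nrow(nodes)), nodes$name)
  q_level <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$name)

  # root is a family of size one tested at q0; descent requires it
  root <- tree$root
  q_level[root] <- q0
  discovered[root] <- p_all[root] <= q0

  # breadth-first descent below discovered nodes; `q` is the threshold
  # for the family formed by the node's children
  queue <- list()
  if (discovered[root]) queue[[1]] <- list(node = root, q = q0)
  while (length(queue) > 0) {
    job <- queue[[1]]
    queue <- queue[-1]
    kids <- family_of(tree, job$node)
    if (length(kids) == 0) next
    q_level[kids] <- job$q
    rej <- bh_within_family(p_all[kids], job$q)
    if (length(rej) == 0) next
    disc_kids <- kids[rej]
    discovered[disc_kids] <- TRUE
    q_next <- if (mode == "strict") {
      job$q * length(rej) / length(kids)
    } else {
      q0
    }
    if (q_next > 0) {
      for (k in disc_kids) {
        queue[[length(queue) + 1]] <- list(node = k, q = q_next)
      }
    }
  }

  parent_of <- stats::setNames(nodes$parent, nodes$name)
  parent_disc <- ifelse(is.na(parent_of[nodes$name]), NA,
                        unname(discovered[parent_of[nodes$name]]))
  report <- tibble::tibble(
    region = nodes$name,
    level = nodes$level,
    p = unname(p_all[nodes$name]),
    family_method = family_method,
    q_level = unname(q_level[nodes$name]),
    discovered = unname(discovered[nodes$name]),
    parent_discovered = parent_disc,
    path_to_root = vapply(nodes$name, function(r)
      paste(path_to_root(tree, r), collapse = ";"), character(1)))
  report <- dplyr::arrange(report, .data$level, .data$region)

  structure(list(report = report, q0 = q0, mode = mode,
                 family_method = family_method,
                 discovered = nodes$name[discovered[nodes$name]]),
            class = "hier_fdr")
}

#' @export
print.hier_fdr <- function(x, ...) {
  cat("<hier_fdr> ", x$family_method, " families, ", x$mode,
      " mode, q0 = ", x$q0, "\n", sep = "")
  cat("  ", length(x$discovered), " discoveries among ",
      nrow(x$report), " regions\n", sep = "")
  if (length(x$discovered) > 0) {
    cat("  discovered:", paste(x$discovered, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.hier_fdr <- function(x, ...) x$report

#' @export
glance.hier_fdr <- function(x, ...) {
  tibble::tibble(q0 = x$q0, mode = x$mode, family_method = x$family_method,
                 n_regions = nrow(x$report),
                 n_discoveries = length(x$discovered))
}

#' Plot a hierarchical testing outcome
#'
#' Regions by tree level against -log10 of their (family) p-value;
#' filled points mark discoveries, the dashed line marks the initial
#' threshold `q0`.
#'
#' @param object A `hier_fdr` object from [run_hierarchy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hier_fdr <- function(object, ...) {
  dat <- object$report
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$level),
                                    y = -log10(pmax(.data$p, 1e-300)),
                                    colour = .data$discovered)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::geom_hline(yintercept = -log10(object$q0),
                        linetype = "dashed") +
    ggplot2::labs(x = "tree level", y = expression(-log[10](p)),
                  colour = "discovered")
}
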