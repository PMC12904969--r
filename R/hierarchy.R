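#' Hierarchical region trees
#'
#' A `region_tree` organises elementary brain areas and nuclei into
#' superordinate structures (gyrus, lobe, cortex, hemisphere, brain).
#' Each group of children sharing one parent is a *family*; families are
#' the units of the hierarchical multiple-testing procedure implemented in
#' [run_hierarchy()].
#'
#' The tree is stored as a node table with one row per region:
#' `name` (unique identifier), `parent` (`NA` for the root), `level`
#' (depth; root = 0), `is_elementary` (leaves carrying their own
#' probabilistic map), and `map_ref` (optional relative path to a NIfTI
#' probability map, elementary nodes only).
#'
#' @param nodes A data frame with columns `name` and `parent`, and
#'   optionally `is_elementary` and `map_ref`.  `parent` must be `NA` for
#'   exactly one row (the root) and name an existing node otherwise.
#'   Child order within a family follows row order.
#'
#' @return A `region_tree` object: a list with elements `nodes` (a tibble
#'   with columns `name`, `parent`, `level`, `is_elementary`, `map_ref`)
#'   and `root` (the root's name).
#' @export
#' @examples
#' tr <- region_tree(data.frame(
#'   name   = c("brain", "left-hemisphere", "right-hemisphere"),
#'   parent = c(NA, "brain", "brain")
#' ))
#' family_of(tr, "brain")
region_tree <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  if (!all(c("name", "parent") %in% names(nodes))) {
    stop("`nodes` must have columns `name` and `parent`", call. = FALSE)
  }
  nodes$name <- as.character(nodes$name)
  nodes$parent <- as.character(nodes$parent)
  if (!"map_ref" %in% names(nodes)) nodes$map_ref <- NA_character_
  nodes$map_ref <- as.character(nodes$map_ref)

  dup <- nodes$name[duplicated(nodes$name)]
  if (length(dup) > 0) {
    stop("duplicate region name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  is_root <- is.na(nodes$parent)
  if (sum(is_root) != 1) {
    stop("exactly one node must have no parent (found ", sum(is_root), ")",
         call. = FALSE)
  }
  missing_parent <- setdiff(nodes$parent[!is_root], nodes$name)
  if (length(missing_parent) > 0) {
    bad <- nodes$name[nodes$parent %in% missing_parent]
    stop("node(s) ", paste(bad, collapse = ", "),
         " reference missing parent(s): ",
         paste(missing_parent, collapse = ", "), call. = FALSE)
  }

  root <- nodes$name[is_root]
  # levels by breadth-first descent; unreached nodes indicate a cycle
  level <- stats::setNames(rep(NA_integer_, nrow(nodes)), nodes$name)
  level[root] <- 0L
  frontier <- root
  while (length(frontier) > 0) {
    kids <- nodes$name[!is.na(nodes$parent) & nodes$parent %in% frontier]
    kids <- kids[is.na(level[kids])]
    if (length(kids) == 0) break
    level[kids] <- level[nodes$parent[match(kids, nodes$name)]] + 1L
    frontier <- kids
  }
  if (anyNA(level)) {
    stop("cycle detected: node(s) unreachable from root: ",
         paste(names(level)[is.na(level)], collapse = ", "), call. = FALSE)
  }
  nodes$level <- unname(level[nodes$name])

  has_children <- nodes$name %in% nodes$parent
  if (!"is_elementary" %in% names(nodes)) {
    nodes$is_elementary <- !has_children
  }
  nodes$is_elementary <- as.logical(nodes$is_elementary)
  bad_elem <- nodes$name[nodes$is_elementary & has_children]
  if (length(bad_elem) > 0) {
    stop("elementary node(s) must not have children: ",
         paste(bad_elem, collapse = ", "), call. = FALSE)
  }
  bad_leaf <- nodes$name[!nodes$is_elementary & !has_children]
  if (length(bad_leaf) > 0) {
    stop("leaf node(s) must be elementary: ",
         paste(bad_leaf, collapse = ", "), call. = FALSE)
  }

  nodes <- nodes[, c("name", "parent", "level", "is_elementary", "map_ref")]
  structure(list(nodes = nodes, root = root), class = "region_tree")
}

#' Read a region hierarchy from JSON
#'
#' The file holds an array of node records
#' `{"name": ..., "parent": ..., "is_elementary": ..., "map_ref": ...}`;
#' `parent` is `null` for the root, and `map_ref` is an optional relative
#' path to a NIfTI probability map for elementary nodes.
#'
#' @param path Path to a hierarchy JSON file.
#' @return A validated [region_tree()].
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("hierarchy file not found: ", path, call. = FALSE)
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(recs) || nrow(recs) == 0) {
    stop("hierarchy file must contain a non-empty array of node records",
         call. = FALSE)
  }
  region_tree(recs)
}

#' Write a region hierarchy to JSON
#'
#' @param tree A [region_tree()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(tree, path) {
  stopifnot(inherits(tree, "region_tree"))
  out <- tree$nodes[, c("name", "parent", "is_elementary", "map_ref")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, na = "null", pretty = TRUE)
  invisible(path)
}

#' Family of a region: its children in the tree
#'
#' A family is the set of child regions sharing one parent; it is the unit
#' over which Simes p-values and within-family BH operate.
#'
#' @param tree A [region_tree()].
#' @param parent Name of the parent region.
#' @return Character vector of child names in stored order (empty for a
#'   leaf).
#' @export
family_of <- function(tree, parent) {
  stopifnot(inherits(tree, "region_tree"))
  if (!parent %in% tree$nodes$name) {
    stop("unknown region: ", parent, call. = FALSE)
  }
  tree$nodes$name[!is.na(tree$nodes$parent) & tree$nodes$parent == parent]
}

#' Path from a region up to the root
#'
#' @param tree A [region_tree()].
#' @param region Name of a region.
#' @return Character vector from `region` up to and including the root;
#'   its length equals the region's level + 1.
#' @export
path_to_root <- function(tree, region) {
  stopifnot(inherits(tree, "region_tree"))
  if (!region %in% tree$nodes$name) {
    stop("unknown region: ", region, call. = FALSE)
  }
  path <- region
  cur <- region
  parent <- stats::setNames(tree$nodes$parent, tree$nodes$name)
  while (!is.na(parent[[cur]])) {
    cur <- parent[[cur]]
    path <- c(path, cur)
  }
  path
}

#' Elementary (leaf) regions of a tree
#' @param tree A [region_tree()].
#' @return Character vector of elementary region names in stored order.
#' @export
elementary_regions <- function(tree) {
  stopifnot(inherits(tree, "region_tree"))
  tree$nodes$name[tree$nodes$is_elementary]
}

# all elementary descendants of `region` (region itself if elementary)
elementary_descendants <- function(tree, region) {
  if (!region %in% tree$nodes$name) {
    stop("unknown region: ", region, call. = FALSE)
  }
  acc <- character(0)
  stack <- region
  while (length(stack) > 0) {
    cur <- stack[[1]]
    stack <- stack[-1]
    kids <- family_of(tree, cur)
    if (length(kids) == 0) acc <- c(acc, cur) else stack <- c(stack, kids)
  }
  acc
}

#' @export
print.region_tree <- function(x, ...) {
  n_elem <- sum(x$nodes$is_elementary)
  cat("<region_tree> ", nrow(x$nodes), " regions (", n_elem,
      " elementary), depth ", max(x$nodes$level),
      ", root '", x$root, "'\n", sep = "")
  invisible(x)
}

#' Bundled toy region hierarchy
#'
#' A small bilateral brain-like hierarchy used for simulation studies and
#' examples: brain > telencephalon / brainstem / cerebellum > hemispheric
#' cortices and lobes > gyri > cytoarchitectonic-style areas, 39 regions
#' (21 elementary) over 6 levels.  It mimics the *structure* of
#' cytoarchitectonic atlas hierarchies without claiming anatomical
#' fidelity.
#'
#' @return A [region_tree()].
#' @export
#' @examples
#' toy_hierarchy()
toy_hierarchy <- function() {
  n <- function(name, parent) data.frame(name = name, parent = parent)
  side <- function(h) {
    pre <- paste0(h, "-")
    rbind(
      n(paste0(pre, "cerebral-cortex"), "telencephalon"),
      n(paste0(pre, "frontal-lobe"), paste0(pre, "cerebral-cortex")),
      n(paste0(pre, "temporal-lobe"), paste0(pre, "cerebral-cortex")),
      n(paste0(pre, "precentral-gyrus"), paste0(pre, "frontal-lobe")),
      n(paste0(pre, "orbitofrontal-cortex"), paste0(pre, "frontal-lobe")),
      n(paste0(pre, "superior-temporal-gyrus"), paste0(pre, "temporal-lobe")),
      n(paste0(pre, "area-6d1"), paste0(pre, "precentral-gyrus")),
      n(paste0(pre, "area-6d2"), paste0(pre, "precentral-gyrus")),
      n(paste0(pre, "area-fo1"), paste0(pre, "orbitofrontal-cortex")),
      n(paste0(pre, "area-fo2"), paste0(pre, "orbitofrontal-cortex")),
      n(paste0(pre, "area-fo3"), paste0(pre, "orbitofrontal-cortex")),
      n(paste0(pre, "area-te1"), paste0(pre, "superior-temporal-gyrus")),
      n(paste0(pre, "area-te2"), paste0(pre, "superior-temporal-gyrus"))
    )
  }
  nodes <- rbind(
    n("brain", NA),
    n("telencephalon", "brain"),
    n("brainstem", "brain"),
    n("cerebellum", "brain"),
    side("left"), side("right"),
    n("mesencephalon", "brainstem"),
    n("pons", "brainstem"),
    n("substantia-nigra", "mesencephalon"),
    n("red-nucleus", "mesencephalon"),
    n("left-cerebellar-cortex", "cerebellum"),
    n("right-cerebellar-cortex", "cerebellum"),
    n("cerebellar-nuclei", "cerebellum"),
    n("left-dentate-nucleus", "cerebellar-nuclei"),
    n("right-dentate-nucleus", "cerebellar-nuclei")
  )
  region_tree(nodes)
}
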