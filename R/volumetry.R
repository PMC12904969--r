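#' Local volume ratio maps and probabilistic region maps
#'
#' A deformation-based morphometry pipeline summarises each subject's
#' anatomy as a voxel grid of *local volume ratios* (LVR) in a common
#' reference space: the ratio of subject tissue volume to reference
#' tissue volume at each voxel.  Summing LVR values over a region of the
#' reference brain, weighted by the region's probabilistic map, yields
#' the subject's regional volume in mm^3.
#'
#' @param grid 3-D numeric array of LVR values (dimensionless, >= 0).
#' @param voxel_volume Volume of one voxel in mm^3 (> 0).
#' @param subject Subject identifier.
#' @return An `lvr_map` object.
#' @export
lvr_map <- function(grid, voxel_volume, subject = NA_character_) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3) stop("`grid` must be a 3-D array", call. = FALSE)
  if (!all(is.finite(grid))) stop("LVR values must be finite", call. = FALSE)
  if (any(grid < 0)) stop("LVR values must be non-negative", call. = FALSE)
  if (!is.numeric(voxel_volume) || length(voxel_volume) != 1 ||
      voxel_volume <= 0) {
    stop("`voxel_volume` must be a single positive number", call. = FALSE)
  }
  structure(list(grid = grid, voxel_volume = as.numeric(voxel_volume),
                 subject = as.character(subject)),
            class = "lvr_map")
}

#' @rdname lvr_map
#' @param region Region name the probability map belongs to.
#' @export
prob_map <- function(grid, region = NA_character_) {
  grid <- as.array(grid)
  if (length(dim(grid)) != 3) stop("`grid` must be a 3-D array", call. = FALSE)
  if (any(!is.finite(grid)) || any(grid < 0) || any(grid > 1)) {
    stop("probability values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(grid = grid, region = as.character(region)),
            class = "prob_map")
}

#' Read LVR / probability maps from NIfTI files
#'
#' Voxel volume is taken from the NIfTI header pixel dimensions.  Maps
#' must already live in the common reference space; no reorientation or
#' resampling is attempted.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param subject,region Identifier attached to the returned map.
#' @return An [lvr_map()] or [prob_map()].
#' @export
read_lvr_map <- function(path, subject = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  img <- RNifti::readNifti(path)
  vv <- prod(RNifti::pixdim(img)[1:3])
  lvr_map(as.array(img), voxel_volume = vv, subject = subject)
}

#' @rdname read_lvr_map
#' @export
read_prob_map <- function(path, region = sub("\\.nii(\\.gz)?$", "", basename(path))) {
  img <- RNifti::readNifti(path)
  prob_map(as.array(img), region = region)
}

#' Write a map to a NIfTI file
#'
#' @param map An [lvr_map()] or [prob_map()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @param voxel_size Edge lengths in mm recorded in the header; for an
#'   `lvr_map` the default reproduces its `voxel_volume` as a cube.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, voxel_size = NULL) {
  if (inherits(map, "lvr_map") && is.null(voxel_size)) {
    voxel_size <- rep(map$voxel_volume^(1 / 3), 3)
  }
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  img <- RNifti::asNifti(map$grid)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Regional volume by probability-weighted LVR summation
#'
#' The subject's volume of a region is the sum of the LVR values over the
#' region's voxels in the reference brain, weighted by the probabilistic
#' map, times the voxel volume:
#' `voxel_volume * sum(p(x) * lvr(x))`.
#'
#' @param lvr An [lvr_map()].
#' @param pmap A [prob_map()] on the same grid.
#' @return Volume in mm^3.
#' @export
#' @examples
#' g <- array(1, c(5, 5, 5))
#' p <- array(0, c(5, 5, 5)); p[1:4, 1:4, 1:4] <- 1
#' region_volume(lvr_map(g, 1), prob_map(p))  # 64 mm^3
region_volume <- function(lvr, pmap) {
  stopifnot(inherits(lvr, "lvr_map"), inherits(pmap, "prob_map"))
  if (!identical(dim(lvr$grid), dim(pmap$grid))) {
    stop("grid shapes differ: LVR ", paste(dim(lvr$grid), collapse = "x"),
         " vs probability map ", paste(dim(pmap$grid), collapse = "x"),
         call. = FALSE)
  }
  lvr$voxel_volume * sum(pmap$grid * lvr$grid)
}

#' Aggregate elementary volumes up the region hierarchy
#'
#' Superordinate region volumes are the sums of their children's volumes,
#' computed bottom-up, so that every internal node's volume equals the
#' sum over its elementary descendants (hierarchical conservation).
#'
#' @param tree A [region_tree()].
#' @param elementary A volume table (tibble with a `subject` column and
#'   one column per elementary region, volumes in mm^3) covering every
#'   elementary node of `tree`.
#' @return A tibble with `subject` plus one column per tree node, in
#'   tree order (level, then name).
#' @export
aggregate_volumes <- function(tree, elementary) {
  stopifnot(inherits(tree, "region_tree"))
  elementary <- tibble::as_tibble(elementary)
  leaves <- elementary_regions(tree)
  absent <- setdiff(leaves, names(elementary))
  if (length(absent) > 0) {
    stop("volume table is missing elementary region(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  vols <- list()
  for (r in leaves) vols[[r]] <- as.numeric(elementary[[r]])
  internal <- tree$nodes$name[!tree$nodes$is_elementary]
  internal <- internal[order(tree$nodes$level[match(internal, tree$nodes$name)],
                             decreasing = TRUE)]
  for (r in internal) {
    kids <- family_of(tree, r)
    vols[[r]] <- Reduce(`+`, vols[kids])
  }
  ord <- tree$nodes$name[order(tree$nodes$level, tree$nodes$name)]
  tibble::as_tibble(c(list(subject = elementary$subject), vols[ord]))
}

#' Build a subject-by-region volume table from maps
#'
#' Computes every elementary cell with [region_volume()] and fills in
#' superordinate regions with [aggregate_volumes()].
#'
#' @param tree A [region_tree()].
#' @param lvr_maps Named list of [lvr_map()] (one per subject; names are
#'   subject ids, falling back to each map's `subject` field).
#' @param prob_maps Named list of [prob_map()] covering every elementary
#'   region of `tree`.
#' @return A tibble with `subject` plus one column per tree node.
#' @export
build_volume_table <- function(tree, lvr_maps, prob_maps) {
  stopifnot(inherits(tree, "region_tree"))
  if (is.null(names(lvr_maps)) || any(names(lvr_maps) == "")) {
    names(lvr_maps) <- vapply(lvr_maps, function(m) m$subject, character(1))
  }
  if (anyNA(names(lvr_maps)) || any(names(lvr_maps) == "NA")) {
    stop("every LVR map needs a subject id", call. = FALSE)
  }
  if (is.null(names(prob_maps)) || any(names(prob_maps) == "")) {
    names(prob_maps) <- vapply(prob_maps, function(m) m$region, character(1))
  }
  leaves <- elementary_regions(tree)
  absent <- setdiff(leaves, names(prob_maps))
  if (length(absent) > 0) {
    stop("missing probability map(s) for region(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  elem <- tibble::tibble(subject = names(lvr_maps))
  for (r in leaves) {
    elem[[r]] <- vapply(lvr_maps, region_volume, numeric(1),
                        pmap = prob_maps[[r]])
  }
  aggregate_volumes(tree, elem)
}

#' Read / write a subject-by-region volume table (TSV)
#'
#' Tab-separated, header `subject` followed by region names; volumes in
#' mm^3 written with 6 significant digits.
#'
#' @param path File path.
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_volume_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject = readr::col_character(), .default = readr::col_double()))
}

#' @rdname read_volume_table
#' @param volumes Volume table tibble.
#' @export
write_volume_table <- function(volumes, path) {
  out <- volumes
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  readr::write_tsv(out, path)
  invisible(path)
}
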