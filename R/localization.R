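#' Labeled voxel grid for anatomical assignment
#'
#' Wraps an integer label volume with its voxel-to-world affine (RAS
#' millimeters) and the set of label ids to exclude from assignment
#' (conventionally cerebral white matter and white-matter
#' hypointensities). Label 0 is background and never assigned.
#'
#' @param data 3-D integer array of label ids.
#' @param affine 4x4 matrix mapping 0-based voxel indices (i, j, k, 1)
#'   to world mm.
#' @param label_names optional named character vector (names = ids).
#' @param excluded_labels label ids excluded from assignment.
#' @return object of class `label_grid`.
#' @export
label_grid <- function(data, affine, label_names = NULL,
                       excluded_labels = integer(0)) {
  stopifnot(length(dim(data)) == 3, is.matrix(affine),
            all(dim(affine) == c(4, 4)),
            abs(det(affine[1:3, 1:3])) > 1e-12)
  structure(list(data = data, affine = affine,
                 label_names = label_names,
                 excluded_labels = as.integer(excluded_labels)),
            class = "label_grid")
}

#' Read a NIfTI label volume into a [label_grid()]
#'
#' @param path NIfTI file path.
#' @param ... passed to [label_grid()] (`label_names`,
#'   `excluded_labels`).
#' @return a `label_grid`. Requires the RNifti package.
#' @export
read_label_grid <- function(path, ...) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI volumes requires the RNifti package")
  }
  img <- RNifti::readNifti(path)
  label_grid(array(as.integer(img), dim(img)[1:3]),
             structure(RNifti::xform(img), class = "matrix",
                       dim = c(4, 4)), ...)
}

#' Assign an anatomical label to a contact by distance-weighted voting
#'
#' Searches all atlas voxels whose centers lie within `radius` mm of the
#' contact, removes excluded labels (white matter) and background, gives
#' each remaining voxel a signal-strength weight of `1/r` (capped at 1,
#' so a voxel at the contact itself contributes 1), sums weights per
#' label, and returns the label with the greatest total. Ties go to the
#' lower label id (with a message). Returns NA when the contact is
#' outside the grid or no eligible voxel lies within the sphere.
#'
#' @param contact_xyz length-3 world coordinates, mm.
#' @param grid a [label_grid()].
#' @param radius search-sphere radius, mm (default 5).
#' @param weight "inverse" (default, `min(1, 1/r)`) or "gaussian"
#'   (`exp(-r^2 / (2 (radius/2)^2))`).
#' @return list: `label` (integer id or NA), `name` (if names known),
#'   `scores` (named numeric, per-label summed weights).
#' @export
assign_label <- function(contact_xyz, grid, radius = 5,
                         weight = c("inverse", "gaussian")) {
  weight <- match.arg(weight)
  stopifnot(inherits(grid, "label_grid"), length(contact_xyz) == 3)
  inv <- solve(grid$affine)
  vox <- (inv %*% c(contact_xyz, 1))[1:3]
  dims <- dim(grid$data)
  # conservative bounding box in voxel units
  spacing <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  halfw <- ceiling(radius / spacing) + 1
  rng <- lapply(1:3, function(a) {
    lo <- max(0, floor(vox[a] - halfw[a]))
    hi <- min(dims[a] - 1, ceiling(vox[a] + halfw[a]))
    if (lo > hi) integer(0) else lo:hi
  })
  if (!all(lengths(rng) > 0)) {
    return(list(label = NA_integer_, name = NA_character_,
                scores = numeric(0)))
  }
  ijk <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  world <- t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
  r <- sqrt(rowSums(sweep(world, 2, contact_xyz)^2))
  lab <- grid$data[ijk + 1]
  keep <- r <= radius & lab > 0 & !(lab %in% grid$excluded_labels)
  if (!any(keep)) {
    return(list(label = NA_integer_, name = NA_character_,
                scores = numeric(0)))
  }
  w <- if (weight == "inverse") pmin(1, 1 / r[keep])
  else exp(-r[keep]^2 / (2 * (radius / 2)^2))
  scores <- tapply(w, lab[keep], sum)
  best <- max(scores)
  winners <- as.integer(names(scores)[scores >= best - 1e-12])
  if (length(winners) > 1) {
    message("label tie at contact (", paste(signif(contact_xyz, 4),
                                            collapse = ", "),
            "); using lower id ", min(winners))
  }
  lab_id <- min(winners)
  nm <- if (!is.null(grid$label_names)) {
    unname(grid$label_names[as.character(lab_id)])
  } else NA_character_
  list(label = lab_id, name = nm, scores = c(scores))
}
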