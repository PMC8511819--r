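ball_offsets <- function(radius) {
  if (radius <= 0) return(matrix(integer(), 0, 3))
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2 & !(g$x == 0 & g$y == 0 & g$z == 0), ]
  as.matrix(g)
}

#' Segmentation parameters
#'
#' Thresholds are adaptive with respect to the calibration phantom: the bone
#' threshold is expressed in calibrated density units (g/cm^3) and converted
#' to HU per scan through the fitted calibration model; the implant threshold
#' is an HU constant far above any biological tissue.
#'
#' @param implant_threshold HU; voxels at or above are implant (default 2000).
#' @param bone_threshold g/cm^3 of calibrated density (default 0.15).
#' @param close_radius Morphological close radius for the bone mask, voxels,
#'   isotropic (default 0: the committed phantom needs no hole closing and a
#'   non-zero radius would bridge the thin fracture slab at 2 mm slices).
#' @param smooth_sigma Gaussian mask-smoothing sigma, mm per axis (default 0).
#' @param min_island_size Components of the bone mask smaller than this many
#'   voxels are removed; this is what strips the calibration rods (default 800).
#' @param max_gap_span_mm Largest bridgeable fracture span for the gap fill
#'   rule (default 10).
#' @param priority_order Label priority used by [resolve_priority()].
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(implant_threshold = 2000,
                                bone_threshold = 0.15,
                                close_radius = 0,
                                smooth_sigma = c(0, 0, 0),
                                min_island_size = 800,
                                max_gap_span_mm = 10,
                                priority_order = c("implant", "gap", "bone")) {
  if (!is.finite(implant_threshold) || !is.finite(bone_threshold))
    stop("thresholds must be finite")
  if (close_radius < 0) stop("close_radius must be >= 0")
  if (any(smooth_sigma < 0)) stop("smooth_sigma must be >= 0")
  structure(list(implant_threshold = implant_threshold,
                 bone_threshold = bone_threshold,
                 close_radius = close_radius,
                 smooth_sigma = rep(smooth_sigma, length.out = 3),
                 min_island_size = min_island_size,
                 max_gap_span_mm = max_gap_span_mm,
                 priority_order = priority_order),
            class = "segmentation_params")
}

#' Threshold a calibrated volume into implant and bone masks
#'
#' Implant voxels are those at or above the HU implant threshold; bone voxels
#' are those whose calibrated density reaches the bone threshold and which are
#' not implant. The gap mask is seeded empty here and filled by the
#' directional gap rule in [segment_volume()].
#'
#' @param vol An [image_volume()] of HU.
#' @param cal A `calibration_model`.
#' @param params A [segmentation_params()] list.
#' @return A `mask_set` list of logical arrays `implant`, `bone`, `gap`, plus
#'   a `provenance` character vector.
#' @export
threshold_masks <- function(vol, cal, params = segmentation_params()) {
  implant <- vol$data >= params$implant_threshold
  rho <- apply_calibration(vol, cal)
  bone <- rho$data >= params$bone_threshold & !implant
  structure(list(implant = implant, bone = bone,
                 gap = array(FALSE, dim = dim(vol$data)),
                 provenance = sprintf(
                   "threshold: implant >= %g HU, bone >= %g g/cm^3 (= %.6g HU)",
                   params$implant_threshold, params$bone_threshold,
                   density_to_hu(params$bone_threshold, cal))),
            class = "mask_set")
}

#' Morphological closing with a ball structuring element
#'
#' Dilation followed by erosion with a Euclidean ball of the given radius in
#' voxel units (isotropic). Radius 0 is the identity. Voxels outside the
#' volume are treated as background.
#'
#' @param mask Logical 3-D array.
#' @param radius_voxels Ball radius in voxels.
#' @return Logical 3-D array.
#' @export
morph_close <- function(mask, radius_voxels) {
  if (radius_voxels <= 0) return(mask)
  off <- ball_offsets(radius_voxels)
  d <- dim(mask)
  dil <- cpp_dilate(as.logical(mask), d, off) | as.vector(mask)
  ero <- cpp_erode(dil, d, off)
  array(ero, dim = d)
}

#' Gaussian mask smoothing
#'
#' Filters the binary indicator with a separable (recursive-in-spirit,
#' FFT-free) Gaussian of per-axis sigma in mm, then re-thresholds at 0.5.
#' Sigma 0 on every axis is the identity.
#'
#' @param mask Logical 3-D array.
#' @param sigma_mm Length-3 sigma in mm per axis (anisotropic).
#' @param spacing Length-3 voxel spacing in mm.
#' @return Logical 3-D array.
#' @export
smooth_mask <- function(mask, sigma_mm, spacing) {
  sigma_mm <- rep(sigma_mm, length.out = 3)
  if (all(sigma_mm <= 0)) return(mask)
  f <- array(as.numeric(mask), dim = dim(mask))
  for (a in 1:3) {
    s <- sigma_mm[a] / spacing[a]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    f <- convolve_axis(f, k, a)
  }
  f >= 0.5
}

# zero-padded separable convolution along one axis
convolve_axis <- function(f, kernel, axis) {
  d <- dim(f)
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = d)
  for (j in seq_along(kernel)) {
    shift <- j - r - 1L
    src <- seq_len(d[axis]) + shift
    ok <- src >= 1L & src <= d[axis]
    if (!any(ok)) next
    idx_dst <- which(ok)
    idx_src <- src[ok]
    if (axis == 1) out[idx_dst, , ] <- out[idx_dst, , ] + kernel[j] * f[idx_src, , ]
    else if (axis == 2) out[, idx_dst, ] <- out[, idx_dst, ] + kernel[j] * f[, idx_src, ]
    else out[, , idx_dst] <- out[, , idx_dst] + kernel[j] * f[, , idx_src]
  }
  out
}

#' Remove small connected components (islands)
#'
#' Components are 26-connected. Either all components below `min_size` are
#' removed, or all but the largest (ties broken by first-encounter order).
#'
#' @param mask Logical 3-D array.
#' @param min_size Minimum voxel count to keep.
#' @param keep_largest If `TRUE`, keep only the largest component.
#' @return Logical 3-D array.
#' @export
remove_islands <- function(mask, min_size = 0, keep_largest = FALSE) {
  if (!any(mask)) return(mask)
  lab <- cpp_label_components(as.logical(mask), dim(mask), 26L)
  sizes <- tabulate(lab, nbins = attr(lab, "n_components"))
  keep <- if (keep_largest) which.max(sizes) else which(sizes >= min_size)
  array(lab %in% keep & as.vector(mask), dim = dim(mask))
}

#' Fill enclosed cavities
#'
#' Background components (6-connected) not connected to the volume border
#' become foreground.
#'
#' @param mask Logical 3-D array.
#' @return Logical 3-D array.
#' @export
fill_cavities <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  lab <- array(cpp_label_components(as.vector(bg), d, 6L), dim = d)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg & !(lab %in% border_labels))
}

#' Directional fracture-gap fill between bone fragments
#'
#' A non-bone, non-implant voxel is marked gap iff bone is present on both
#' sides of it along the bone axis (third array axis) within
#' `max_gap_span_mm`, and it lies in a fracture slice: a slice whose bone
#' voxel count is below half the median per-slice bone count over the bone
#' extent. This deterministic rule stands in for the manually checked gap
#' mask of a clinical workflow.
#'
#' @param bone,implant Logical 3-D arrays.
#' @param spacing Voxel spacing (mm).
#' @param max_gap_span_mm Largest bridgeable span (mm).
#' @return Logical 3-D array marking the gap.
#' @export
fill_gap_between_fragments <- function(bone, implant, spacing,
                                       max_gap_span_mm = 10) {
  d <- dim(bone)
  span <- max(1L, floor(max_gap_span_mm / spacing[3]))
  # per-column cumulative presence of bone below/above each slice
  below <- array(FALSE, dim = d)
  above <- array(FALSE, dim = d)
  for (z in seq_len(d[3])) {
    lo <- max(1L, z - span)
    below[, , z] <- apply(bone[, , lo:z, drop = FALSE], c(1, 2), any)
  }
  for (z in seq_len(d[3])) {
    hi <- min(d[3], z + span)
    above[, , z] <- apply(bone[, , z:hi, drop = FALSE], c(1, 2), any)
  }
  candidate <- below & above & !bone & !implant

  slice_counts <- apply(bone, 3, sum)
  occupied <- which(slice_counts > 0)
  if (length(occupied) == 0) return(array(FALSE, dim = d))
  med <- median(slice_counts[min(occupied):max(occupied)])
  fracture_slices <- which(slice_counts < med / 2)
  fracture_slices <- fracture_slices[fracture_slices >= min(occupied) &
                                       fracture_slices <= max(occupied)]
  out <- array(FALSE, dim = d)
  out[, , fracture_slices] <- candidate[, , fracture_slices]
  out
}

#' Resolve overlapping masks into a disjoint label volume
#'
#' Voxels claimed by several masks are assigned to the highest-priority
#' claiming mask; the result is a disjoint labelling (background elsewhere).
#'
#' @param masks A `mask_set` (or plain list) of logical arrays.
#' @param priority_order Character vector of mask names, highest first.
#' @return Integer label array coded per [fracenv_labels()].
#' @export
resolve_priority <- function(masks, priority_order = c("implant", "gap", "bone")) {
  codes <- fracenv_labels()
  unknown <- setdiff(priority_order, names(codes))
  if (length(unknown)) stop("unknown labels in priority order: ",
                            paste(unknown, collapse = ", "))
  if (anyDuplicated(priority_order)) stop("priority order contains duplicates")
  d <- dim(masks[[priority_order[1]]])
  lab <- array(codes[["background"]], dim = d)
  for (nm in rev(priority_order)) {
    m <- masks[[nm]]
    if (is.null(m)) next
    lab[m] <- codes[[nm]]
  }
  lab
}

#' Full segmentation chain
#'
#' Runs the mask-generation sequence on a calibrated volume: adaptive
#' thresholding into implant/bone masks, morphological close and Gaussian
#' smoothing of the bone mask, island removal (which strips the calibration
#' rods), cavity fill, directional gap fill between the fragments, and
#' priority resolution into a disjoint label volume. Every step appends to a
#' provenance log.
#'
#' @param vol An [image_volume()] of HU.
#' @param cal A `calibration_model`.
#' @param params A [segmentation_params()] list.
#' @return List with `labels` (integer array), `masks` (`mask_set`),
#'   and `provenance` (character vector of applied steps).
#' @export
segment_volume <- function(vol, cal, params = segmentation_params()) {
  ms <- threshold_masks(vol, cal, params)
  log <- ms$provenance

  bone <- ms$bone
  if (params$close_radius > 0) {
    bone <- morph_close(bone, params$close_radius)
    log <- c(log, sprintf("morph_close: bone, radius %g voxels", params$close_radius))
  }
  if (any(params$smooth_sigma > 0)) {
    bone <- smooth_mask(bone, params$smooth_sigma, vol$spacing)
    log <- c(log, sprintf("smooth_mask: bone, sigma (%s) mm",
                          paste(params$smooth_sigma, collapse = ", ")))
  }
  bone <- remove_islands(bone, min_size = params$min_island_size)
  log <- c(log, sprintf("remove_islands: bone, min_size %d voxels",
                        as.integer(params$min_island_size)))
  bone <- fill_cavities(bone)
  log <- c(log, "fill_cavities: bone")

  gap <- fill_gap_between_fragments(bone, ms$implant, vol$spacing,
                                    params$max_gap_span_mm)
  log <- c(log, sprintf("fill_gap_between_fragments: span <= %g mm",
                        params$max_gap_span_mm))

  masks <- structure(list(implant = ms$implant, bone = bone, gap = gap),
                     class = "mask_set")
  labels <- resolve_priority(masks, params$priority_order)
  log <- c(log, sprintf("resolve_priority: %s",
                        paste(params$priority_order, collapse = " > ")))

  # invariants asserted on every run: the labelling is disjoint and every
  # voxel of the top-priority mask kept its label
  codes <- fracenv_labels()
  stopifnot(sum(labels == codes[[params$priority_order[1]]]) ==
              sum(masks[[params$priority_order[1]]]))
  claimed <- masks$implant | masks$bone | masks$gap
  stopifnot(sum(labels != codes[["background"]]) == sum(claimed))

  list(labels = labels, masks = masks, provenance = log)
}

#' Dice similarity coefficient between two binary masks
#' @param a,b Logical arrays of equal dimension.
#' @return Dice coefficient in `[0, 1]`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
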