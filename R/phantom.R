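#' Specification of the synthetic fractured-tibia phantom
#'
#' Describes an idealized, axis-aligned fractured tibia: concentric cylinders
#' (cortical shell, trabecular ring, medullary canal with marrow), an
#' intramedullary nail with transverse locking screws, a soft fracture gap of
#' configurable width and obliquity, and six calibration rods of known
#' equivalent mineral density placed outside the leg. Voxel HU values follow
#' `HU = hu_slope * rho_eqm + hu_intercept` plus Gaussian noise for bone and
#' rods; implant, gap, marrow and background carry constant HU.
#'
#' Defaults describe the committed study phantom: a 56 x 56 x 40 voxel volume
#' at 1 x 1 x 2 mm spacing (56 x 56 x 80 mm), bone occupying z = 8-72 mm,
#' 9 mm nail, two distal and two proximal locking screws, a 3 mm transverse
#' gap at mid-shaft, and a 0-0.8 g/cm^3 six-rod density ladder.
#'
#' @param ... Overrides for any field (see the function body for the full
#'   list and defaults). Distances in mm, densities in g/cm^3, HU values in
#'   Hounsfield units.
#' @return A validated object of class `phantom_spec`.
#' @export
phantom_spec <- function(...) {
  spec <- list(
    volume_shape = c(56L, 56L, 40L),
    voxel_spacing = c(1, 1, 2),
    origin = c(0, 0, 0),
    cortical_outer_radius = 9,
    cortical_inner_radius = 7.5,
    canal_radius = 6,
    nail_diameter = 9,
    nail_z_range = c(12, 68),
    screw_spec = data.frame(z_mm = c(17, 25, 55, 63), diameter_mm = 4),
    gap_width = 3,
    gap_obliquity = 0,
    gap_center_mm = 40,
    bone_z_range = c(8, 72),
    rod_densities = c(0, 0.1, 0.2, 0.4, 0.6, 0.8),
    rod_radius = 3,
    rod_offset_mm = 18,
    rod_z_fraction = c(0.3, 0.7),
    hu_slope = 1000,
    hu_intercept = 0,
    noise_sd = 5,
    implant_hu = 3000,
    gap_hu = 20,
    background_hu = -100,
    marrow_hu = 30,
    cortical_density = 0.8,
    trabecular_density = 0.2,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(spec))
  if (length(unknown)) stop("unknown phantom_spec fields: ",
                            paste(unknown, collapse = ", "))
  spec[names(over)] <- over
  spec <- structure(spec, class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (!(canal_radius < cortical_inner_radius &&
          cortical_inner_radius < cortical_outer_radius))
      stop("radii must satisfy canal < cortical_inner < cortical_outer")
    if (nail_diameter / 2 > canal_radius)
      stop("nail does not fit the medullary canal (nail_diameter/2 > canal_radius)")
    if (length(rod_densities) != 6L)
      stop("exactly six calibration rod densities are required")
    if (any(diff(rod_densities) <= 0))
      stop("rod densities must be strictly increasing")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (gap_width <= 0) stop("gap_width must be > 0")
    if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive")
    extent <- origin + (volume_shape - 1) * voxel_spacing
    if (bone_z_range[1] < origin[3] || bone_z_range[2] > extent[3])
      stop("geometry error: bone z-range does not fit the volume")
    axis_c <- origin[1:2] + (volume_shape[1:2] - 1) * voxel_spacing[1:2] / 2
    rod_y <- axis_c[2] + rod_offset_mm
    if (rod_y + rod_radius > extent[2] || rod_y - rod_radius < origin[2])
      stop("geometry error: calibration rods do not fit the volume")
    if (rod_offset_mm < cortical_outer_radius + rod_radius)
      stop("geometry error: calibration rods overlap the bone")
    if (axis_c[1] - cortical_outer_radius < origin[1] ||
        axis_c[1] + cortical_outer_radius > extent[1])
      stop("geometry error: bone does not fit the volume")
  })
  invisible(spec)
}

#' Outward normal of the fracture plane for a phantom spec
#' @param spec A `phantom_spec`.
#' @return Unit length-3 vector (tilt about the y axis by `gap_obliquity`).
#' @export
fracture_normal <- function(spec) {
  th <- spec$gap_obliquity * pi / 180
  c(sin(th), 0, cos(th))
}

#' Generate a synthetic calibrated CT-like volume with ground truth
#'
#' Rasterizes the phantom described by `spec` on the voxel grid. A voxel
#' belongs to a region iff its centre point does; overlaps are resolved with
#' priority implant > gap > bone > rod > background. Bone and rod voxels get
#' `HU = hu_slope * rho_eqm + hu_intercept + N(0, noise_sd)`; implant, gap,
#' marrow and background voxels carry their constant HU. The generator is
#' deterministic for a fixed `spec$seed`.
#'
#' @param spec A `phantom_spec`.
#' @return List with `volume` (an [image_volume()] of HU) and `truth`, a list
#'   holding `labels` (integer 3-D array coded per [fracenv_labels()]),
#'   `density` (3-D array of true equivalent mineral density, g/cm^3, zero
#'   outside bone and rods), `hu_law` (`slope`, `intercept`), and `seed`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  d <- spec$volume_shape
  sp <- spec$voxel_spacing
  n <- prod(d)
  codes <- fracenv_labels()

  cx <- spec$origin[1] + (seq_len(d[1]) - 1) * sp[1]
  cy <- spec$origin[2] + (seq_len(d[2]) - 1) * sp[2]
  cz <- spec$origin[3] + (seq_len(d[3]) - 1) * sp[3]
  axis_c <- spec$origin[1:2] + (d[1:2] - 1) * sp[1:2] / 2

  X <- array(rep(cx, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(cz, each = d[1] * d[2]), dim = d)
  R <- sqrt((X - axis_c[1])^2 + (Y - axis_c[2])^2)

  in_bone_z <- Z >= spec$bone_z_range[1] & Z <= spec$bone_z_range[2]
  nrm <- fracture_normal(spec)
  plane_dist <- (X - axis_c[1]) * nrm[1] + (Y - axis_c[2]) * nrm[2] +
    (Z - spec$gap_center_mm) * nrm[3]
  in_slab <- abs(plane_dist) <= spec$gap_width / 2

  nail <- R < spec$nail_diameter / 2 &
    Z >= spec$nail_z_range[1] & Z <= spec$nail_z_range[2]
  screws <- array(FALSE, dim = d)
  if (nrow(spec$screw_spec) > 0) {
    for (s in seq_len(nrow(spec$screw_spec))) {
      zs <- spec$screw_spec$z_mm[s]
      rs <- spec$screw_spec$diameter_mm[s] / 2
      screws <- screws |
        (sqrt((Y - axis_c[2])^2 + (Z - zs)^2) < rs &
           abs(X - axis_c[1]) <= spec$cortical_outer_radius + 1)
    }
  }
  implant <- nail | screws

  annulus <- R >= spec$canal_radius & R < spec$cortical_outer_radius
  gap <- annulus & in_slab & in_bone_z & !implant
  cortical <- R >= spec$cortical_inner_radius & R < spec$cortical_outer_radius &
    in_bone_z & !gap & !implant
  trabecular <- R >= spec$canal_radius & R < spec$cortical_inner_radius &
    in_bone_z & !gap & !implant
  marrow <- R < spec$canal_radius & in_bone_z & !implant & !gap

  labels <- array(codes[["background"]], dim = d)
  density <- array(0, dim = d)
  hu <- array(spec$background_hu, dim = d)

  rod_y <- axis_c[2] + spec$rod_offset_mm
  zext <- spec$origin[3] + (d[3] - 1) * sp[3]
  rod_z <- spec$origin[3] + spec$rod_z_fraction * (zext - spec$origin[3])
  xext <- spec$origin[1] + (d[1] - 1) * sp[1]
  pad <- spec$rod_radius + 1.5
  rod_x <- seq(spec$origin[1] + pad, xext - pad, length.out = 6)
  rods <- vector("list", 6)
  for (k in 1:6) {
    rods[[k]] <- sqrt((X - rod_x[k])^2 + (Y - rod_y)^2) < spec$rod_radius &
      Z >= rod_z[1] & Z <= rod_z[2]
  }

  # priority: implant > gap > bone > rod > background
  for (k in 1:6) {
    m <- rods[[k]]
    labels[m] <- codes[[paste0("rod_", k)]]
    density[m] <- spec$rod_densities[k]
  }
  labels[trabecular] <- codes[["bone"]]
  density[trabecular] <- spec$trabecular_density
  labels[cortical] <- codes[["bone"]]
  density[cortical] <- spec$cortical_density
  labels[gap] <- codes[["gap"]]
  labels[implant] <- codes[["implant"]]
  density[gap] <- 0
  density[implant] <- 0

  noisy <- labels == codes[["bone"]] | labels >= codes[["rod_1"]]
  hu[noisy] <- spec$hu_slope * density[noisy] + spec$hu_intercept
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    hu[noisy] <- hu[noisy] + rnorm(sum(noisy), 0, spec$noise_sd)
  }
  hu[marrow & labels == codes[["background"]]] <- spec$marrow_hu
  hu[labels == codes[["gap"]]] <- spec$gap_hu
  hu[labels == codes[["implant"]]] <- spec$implant_hu

  list(
    volume = image_volume(hu, spacing = sp, origin = spec$origin),
    truth = list(labels = labels, density = density,
                 hu_law = list(slope = spec$hu_slope,
                               intercept = spec$hu_intercept),
                 spec = spec, seed = spec$seed)
  )
}
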