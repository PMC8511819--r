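#' Ash density from equivalent mineral density
#'
#' `rho_ash = 1.22 * rho_eqm + 0.0523` (g/cm^3), the standard linear relation
#' between hydroxyapatite-equivalent density read from a calibration phantom
#' and the ash (mineral) density entering density-elasticity laws.
#'
#' @param rho_eqm Equivalent mineral density, g/cm^3, non-negative.
#' @return Ash density, g/cm^3.
#' @export
ash_density <- function(rho_eqm) {
  if (any(rho_eqm < 0)) stop("rho_eqm must be >= 0 (clamp calibrated densities upstream)")
  1.22 * rho_eqm + 0.0523
}

#' Cortical density-elasticity power law
#'
#' `E_cort = 10200 * rho_ash^2.01` (MPa).
#'
#' @param rho_ash Ash density, g/cm^3, non-negative.
#' @return Young's modulus, MPa.
#' @export
modulus_cortical <- function(rho_ash) {
  if (any(rho_ash < 0)) stop("rho_ash must be >= 0")
  10200 * rho_ash^2.01
}

#' Trabecular density-elasticity linear law
#'
#' `E_trab = 5307 * rho_ash + 469` (MPa).
#'
#' @param rho_ash Ash density, g/cm^3, non-negative.
#' @return Young's modulus, MPa.
#' @export
modulus_trabecular <- function(rho_ash) {
  if (any(rho_ash < 0)) stop("rho_ash must be >= 0")
  5307 * rho_ash + 469
}

#' Material card: homogeneous constants and classification settings
#'
#' Implant (titanium nail and screws): E = 108000 MPa, nu = 0.37, with ASTM
#' F1472-14 minimum yield 860 MPa and tensile 930 MPa strengths used for
#' advisory reporting only. Fracture gap (initial connective tissue):
#' E = 3 MPa, nu = 0.4. Bone: fixed nu = 0.30, Young's modulus heterogeneous
#' via the density-elasticity laws; elements at or above
#' `cortical_ash_threshold` (g/cm^3 ash density) take the cortical power law,
#' below it the trabecular linear law.
#'
#' @param implant_E,implant_nu,gap_E,gap_nu,bone_nu Elastic constants.
#' @param yield_strength,tensile_strength MPa, reporting thresholds.
#' @param cortical_ash_threshold g/cm^3 (default 0.6).
#' @return A `material_card` list.
#' @export
material_card <- function(implant_E = 108000, implant_nu = 0.37,
                          gap_E = 3, gap_nu = 0.4, bone_nu = 0.30,
                          yield_strength = 860, tensile_strength = 930,
                          cortical_ash_threshold = 0.6) {
  structure(list(implant_E = implant_E, implant_nu = implant_nu,
                 gap_E = gap_E, gap_nu = gap_nu, bone_nu = bone_nu,
                 yield_strength = yield_strength,
                 tensile_strength = tensile_strength,
                 cortical_ash_threshold = cortical_ash_threshold),
            class = "material_card")
}

#' Convert a label volume into a conforming tetrahedral mesh
#'
#' Each foreground voxel is split into 6 tetrahedra by the Kuhn subdivision
#' around the cube's main diagonal; because every voxel uses the same
#' diagonal orientation, faces of neighbouring voxels triangulate identically
#' and the global mesh is conforming. The subdivision is volume-exact. Order
#' 2 promotes every unique element edge to a midside node at the straight
#' edge midpoint (quadratic tetrahedra of C3D10 type).
#'
#' @param labels Integer 3-D label array.
#' @param spacing Voxel spacing, mm.
#' @param order 1 (TET4) or 2 (TET10).
#' @param foreground Integer label codes to mesh; defaults to bone, gap and
#'   implant.
#' @param origin Physical position of the centre of voxel `[1,1,1]`, mm.
#' @return A `tet_mesh` list: `nodes` (n x 3 mm), `elements` (ne x 4 or
#'   ne x 10, 1-based), `part` (label code per element), `voxel` (linear
#'   source-voxel index per element), `order`, `spacing`, `origin`.
#' @export
voxels_to_tets <- function(labels, spacing, order = 1,
                           foreground = fracenv_labels()[c("bone", "gap", "implant")],
                           origin = c(0, 0, 0)) {
  if (!order %in% c(1, 2)) stop("order must be 1 (TET4) or 2 (TET10)")
  res <- cpp_voxels_to_tets(as.integer(labels), dim(labels),
                            as.integer(foreground), as.integer(order))
  # grid coords are voxel-corner indices; corner (0,0,0) sits half a voxel
  # below the centre of voxel [1,1,1]
  nodes <- sweep(res$nodes_grid, 2, spacing, `*`)
  nodes <- sweep(nodes, 2, origin - spacing / 2, `+`)
  structure(list(nodes = nodes, elements = res$elements, part = res$part,
                 voxel = res$voxel, order = as.integer(order),
                 spacing = spacing, origin = origin,
                 label_dim = dim(labels)),
            class = "tet_mesh")
}

#' @exportS3Method base::print
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d TET%d elements, %d parts\n",
              nrow(x$nodes), nrow(x$elements), if (x$order == 2) 10 else 4,
              length(unique(x$part))))
  invisible(x)
}

#' Total element volume of a tetrahedral mesh
#' @param mesh A `tet_mesh`.
#' @return Per-element signed volumes (mm^3); all positive for a valid mesh.
#' @export
element_volumes <- function(mesh) {
  el <- mesh$elements
  a <- mesh$nodes[el[, 1], , drop = FALSE]
  b <- mesh$nodes[el[, 2], , drop = FALSE] - a
  c_ <- mesh$nodes[el[, 3], , drop = FALSE] - a
  d <- mesh$nodes[el[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
     b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
     b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Assign per-element materials
#'
#' Implant and gap elements receive their homogeneous constants from the
#' material card. Bone elements sample the calibrated equivalent mineral
#' density at the voxel containing the element centroid, convert it to ash
#' density, and take the cortical power law when the ash density reaches
#' `card$cortical_ash_threshold`, otherwise the trabecular linear law; the
#' Poisson ratio is fixed per tissue class. Note the two laws do not agree at
#' the threshold: the modulus is intentionally discontinuous there, as the
#' two relations come from different tissue regressions.
#'
#' @param mesh A `tet_mesh`.
#' @param density_vol An [image_volume()] of equivalent mineral density
#'   (g/cm^3), sharing the coordinate frame of the mesh.
#' @param card A [material_card()].
#' @return A `material_field` data.frame with columns `young_modulus` (MPa),
#'   `poisson_ratio`, `ash_density` (g/cm^3, NA outside bone), `tissue_class`.
#' @export
assign_materials <- function(mesh, density_vol, card = material_card()) {
  codes <- fracenv_labels()
  ne <- nrow(mesh$elements)
  E <- numeric(ne)
  nu <- numeric(ne)
  rho_ash <- rep(NA_real_, ne)
  tclass <- character(ne)

  is_implant <- mesh$part == codes[["implant"]]
  is_gap <- mesh$part == codes[["gap"]]
  is_bone <- mesh$part == codes[["bone"]]

  E[is_implant] <- card$implant_E; nu[is_implant] <- card$implant_nu
  tclass[is_implant] <- "implant"
  E[is_gap] <- card$gap_E; nu[is_gap] <- card$gap_nu
  tclass[is_gap] <- "gap"

  if (any(is_bone)) {
    el <- mesh$elements[is_bone, 1:4, drop = FALSE]
    centroid <- (mesh$nodes[el[, 1], , drop = FALSE] +
                   mesh$nodes[el[, 2], , drop = FALSE] +
                   mesh$nodes[el[, 3], , drop = FALSE] +
                   mesh$nodes[el[, 4], , drop = FALSE]) / 4
    d <- dim(density_vol$data)
    vi <- sapply(1:3, function(a)
      floor((centroid[, a] - (density_vol$origin[a] - density_vol$spacing[a] / 2)) /
              density_vol$spacing[a]) + 1)
    if (any(vi < 1) || any(sweep(vi, 2, d, `>`)))
      stop("element centroid outside the density volume")
    lin <- vi[, 1] + d[1] * (vi[, 2] - 1) + d[1] * d[2] * (vi[, 3] - 1)
    rho <- pmax(density_vol$data[lin], 0)
    ra <- ash_density(rho)
    cortical <- ra >= card$cortical_ash_threshold
    Eb <- ifelse(cortical, modulus_cortical(ra), modulus_trabecular(ra))
    E[is_bone] <- Eb
    nu[is_bone] <- card$bone_nu
    rho_ash[is_bone] <- ra
    tclass[is_bone] <- ifelse(cortical, "cortical", "trabecular")
  }

  if (any(E <= 0) || any(nu <= 0) || any(nu >= 0.5))
    stop("invalid material assignment (need E > 0 and 0 < nu < 0.5)")
  structure(data.frame(young_modulus = E, poisson_ratio = nu,
                       ash_density = rho_ash, tissue_class = tclass,
                       stringsAsFactors = FALSE),
            class = c("material_field", "data.frame"))
}
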