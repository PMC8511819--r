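voigt_to_tensor <- function(v, engineering = TRUE) {
  s <- if (engineering) 0.5 else 1
  matrix(c(v[1], s * v[4], s * v[6],
           s * v[4], v[2], s * v[5],
           s * v[6], s * v[5], v[3]), 3, 3)
}

#' Volumetric strain
#'
#' Trace of the strain tensor (relative volume change).
#'
#' @param eps Length-6 Voigt strain vector or ne x 6 matrix
#'   (xx, yy, zz, xy, yz, xz; shear convention irrelevant for the trace).
#' @return Dimensionless volumetric strain per row.
#' @export
volumetric_strain <- function(eps) {
  if (is.null(dim(eps))) eps <- matrix(eps, nrow = 1)
  eps[, 1] + eps[, 2] + eps[, 3]
}

#' Octahedral shear strain
#'
#' `gamma_oct = (2/3) sqrt((e1-e2)^2 + (e2-e3)^2 + (e3-e1)^2)` from the
#' principal strains, obtained by symmetric eigendecomposition of each strain
#' tensor (ties resolved by the sorted eigenvalues).
#'
#' @param eps Length-6 Voigt strain vector or ne x 6 matrix with engineering
#'   shear components (gamma = 2 eps).
#' @return Non-negative octahedral shear strain per row.
#' @export
octahedral_shear_strain <- function(eps) {
  if (is.null(dim(eps))) eps <- matrix(eps, nrow = 1)
  apply(eps, 1, function(v) {
    ev <- eigen(voigt_to_tensor(v), symmetric = TRUE, only.values = TRUE)$values
    (2 / 3) * sqrt((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 + (ev[3] - ev[1])^2)
  })
}

#' Hydrostatic pressure
#'
#' `p = -tr(sigma) / 3`; compression positive (documented sign convention:
#' a compressed element has positive hydrostatic pressure).
#'
#' @param sigma Length-6 Voigt stress vector or ne x 6 matrix (MPa).
#' @return Hydrostatic pressure (MPa) per row.
#' @export
hydrostatic_pressure <- function(sigma) {
  if (is.null(dim(sigma))) sigma <- matrix(sigma, nrow = 1)
  -(sigma[, 1] + sigma[, 2] + sigma[, 3]) / 3
}

#' Per-element strain invariants
#'
#' @param sol A `field_solution`.
#' @return data.frame with `eps_vol`, `gamma_oct`, `p_hydro` per element.
#' @export
strain_invariants <- function(sol) {
  data.frame(eps_vol = volumetric_strain(sol$strain),
             gamma_oct = octahedral_shear_strain(sol$strain),
             p_hydro = hydrostatic_pressure(sol$stress))
}

#' Tissue-differentiation (healing-zone) rule
#'
#' Ordered, first-match-wins rectangular zones in the (octahedral shear
#' strain, hydrostatic pressure) plane, in the tradition of strain/pressure
#' tissue-differentiation diagrams: small distortional strain and small
#' pressure magnitude favour intramembranous ossification; compressive
#' pressure beyond `p_endo` with moderate strain favours endochondral
#' ossification; everything beyond is excessive connective-tissue stimulus.
#' An optional low-stimulus band distinguishes the range between bone
#' resorption and bone formation. The numeric boundaries are configurable
#' literature defaults, not measured constants; every report echoes the rule
#' actually used.
#'
#' @param gamma_intramembranous Max octahedral shear strain for
#'   intramembranous ossification (default 0.05).
#' @param gamma_endochondral Max octahedral shear strain for endochondral
#'   ossification (default 0.15).
#' @param p_limit Hydrostatic pressure magnitude limit for intramembranous
#'   ossification, MPa (default 0.15).
#' @param low_stimulus_band Include the resorption/formation boundary band
#'   (default `TRUE`).
#' @param gamma_low,p_low Bounds of the low-stimulus band (defaults 0.002 and
#'   0.02 MPa).
#' @return A `healing_zone_rule` list of ordered zones, validated to cover
#'   the plane.
#' @export
healing_zone_rule <- function(gamma_intramembranous = 0.05,
                              gamma_endochondral = 0.15,
                              p_limit = 0.15,
                              low_stimulus_band = TRUE,
                              gamma_low = 0.002, p_low = 0.02) {
  zones <- list()
  if (low_stimulus_band)
    zones <- c(zones, list(list(name = "resorption_band",
                                gamma = c(0, gamma_low),
                                p = c(-p_low, p_low))))
  zones <- c(zones, list(
    list(name = "intramembranous_ossification",
         gamma = c(0, gamma_intramembranous), p = c(-p_limit, p_limit)),
    list(name = "endochondral_ossification",
         gamma = c(0, gamma_endochondral), p = c(p_limit, Inf)),
    list(name = "connective_tissue_excess",
         gamma = c(0, Inf), p = c(-Inf, Inf))
  ))
  rule <- structure(list(zones = zones), class = "healing_zone_rule")
  validate_zone_rule(rule)
  rule
}

validate_zone_rule <- function(rule) {
  gammas <- c(0, 1e-4, 0.01, 0.049, 0.05, 0.051, 0.1, 0.15, 0.2, 0.5, 1, 5)
  ps <- c(-5, -1, -0.2, -0.15, -0.1, 0, 0.02, 0.1, 0.15, 0.16, 1, 5)
  grid <- expand.grid(gamma = gammas, p = ps)
  lab <- classify_points(grid$gamma, grid$p, rule, check = FALSE)
  if (anyNA(lab))
    stop("healing-zone rule does not cover the (gamma_oct, p) plane")
  invisible(rule)
}

classify_points <- function(gamma, p, rule, check = TRUE) {
  out <- rep(NA_character_, length(gamma))
  for (z in rule$zones) {
    hit <- is.na(out) &
      gamma >= z$gamma[1] & gamma <= z$gamma[2] &
      p >= z$p[1] & p <= z$p[2]
    out[hit] <- z$name
  }
  if (check && anyNA(out)) stop("healing-zone rule left elements unclassified")
  out
}

#' Classify elements into healing zones
#'
#' Deterministic first-match labelling of per-element invariants against an
#' ordered healing-zone rule.
#'
#' @param inv data.frame from [strain_invariants()] (needs `gamma_oct`,
#'   `p_hydro`).
#' @param rule A [healing_zone_rule()].
#' @return Character vector of zone names, one per element.
#' @export
classify_elements <- function(inv, rule = healing_zone_rule()) {
  validate_zone_rule(rule)
  classify_points(inv$gamma_oct, inv$p_hydro, rule)
}

#' Zone counts, fractions and headline percentages
#'
#' @param labels Character vector of zone names.
#' @param total Total element count the fractions refer to (defaults to
#'   `length(labels)`).
#' @return data.frame with `zone`, `count`, `fraction` (full precision) and
#'   `percent` (headline percentage rounded to the nearest integer).
#' @export
zone_fractions <- function(labels, total = length(labels)) {
  zones <- unique(labels)
  counts <- vapply(zones, function(z) sum(labels == z), 0L)
  out <- data.frame(zone = zones, count = as.integer(counts),
                    fraction = counts / total,
                    percent = round(100 * counts / total))
  stopifnot(abs(sum(out$fraction) - 1) < 1e-12 || total != length(labels))
  out[order(-out$count), , drop = FALSE]
}

#' Interfragmentary movement across the fracture gap
#'
#' The gap's two bone interfaces are the bone nodes shared with gap
#' elements, split into a proximal and a distal set by their position along
#' the fracture-plane normal. IFM is the difference of the mean nodal
#' displacement of the proximal and distal interface, decomposed into an
#' axial component (along the normal, magnitude) and a shear component
#' (in-plane magnitude).
#'
#' @param sol A `field_solution`.
#' @param mesh The `tet_mesh`.
#' @param normal Unit fracture-plane normal (default transverse, `c(0,0,1)`).
#' @return List with `axial_mm`, `shear_mm`, and the two mean interface
#'   displacement vectors.
#' @export
interfragmentary_movement <- function(sol, mesh, normal = c(0, 0, 1)) {
  codes <- fracenv_labels()
  normal <- normal / sqrt(sum(normal^2))
  gap_el <- mesh$part == codes[["gap"]]
  bone_el <- mesh$part == codes[["bone"]]
  if (!any(gap_el) || !any(bone_el))
    stop("gap interfaces not identifiable: need both gap and bone elements")
  gap_nodes <- unique(as.vector(mesh$elements[gap_el, , drop = FALSE]))
  bone_nodes <- unique(as.vector(mesh$elements[bone_el, , drop = FALSE]))
  iface <- intersect(gap_nodes, bone_nodes)
  if (length(iface) < 2L) stop("gap interfaces not identifiable")
  s <- as.numeric(mesh$nodes[iface, , drop = FALSE] %*% normal)
  mid <- mean(range(s))
  prox <- iface[s > mid]
  dist <- iface[s <= mid]
  if (length(prox) == 0L || length(dist) == 0L)
    stop("gap interfaces not identifiable: one-sided interface")
  up <- colMeans(sol$displacement[prox, , drop = FALSE])
  ud <- colMeans(sol$displacement[dist, , drop = FALSE])
  ifm <- up - ud
  ax <- sum(ifm * normal)
  shear_vec <- ifm - ax * normal
  list(axial_mm = abs(ax), shear_mm = sqrt(sum(shear_vec^2)),
       proximal_mean = up, distal_mean = ud)
}

#' Mechanobiological report for a solved scenario
#'
#' Combines per-element invariants, healing-zone classification of the
#' fracture-gap elements, zone counts/fractions, interfragmentary movement,
#' and per-part maximum von Mises stress.
#'
#' @param sol A `field_solution`.
#' @param mesh The `tet_mesh`.
#' @param rule A [healing_zone_rule()].
#' @param normal Fracture-plane normal.
#' @return A `mechano_report` list.
#' @export
mechano_report <- function(sol, mesh, rule = healing_zone_rule(),
                           normal = c(0, 0, 1)) {
  codes <- fracenv_labels()
  inv <- strain_invariants(sol)
  gap_idx <- which(mesh$part == codes[["gap"]])
  if (length(gap_idx) == 0L) stop("no gap elements in mesh")
  gap_zones <- classify_elements(inv[gap_idx, , drop = FALSE], rule)
  zf <- zone_fractions(gap_zones)
  stopifnot(sum(zf$count) == length(gap_idx))
  structure(list(
    invariants = inv,
    gap_elements = gap_idx,
    gap_zones = gap_zones,
    zone_summary = zf,
    n_gap_elements = length(gap_idx),
    ifm = interfragmentary_movement(sol, mesh, normal),
    max_von_mises = max_von_mises_by_part(sol, mesh),
    rule = rule,
    sign_convention = "hydrostatic pressure: compression positive"),
    class = "mechano_report")
}

#' @exportS3Method base::print
print.mechano_report <- function(x, ...) {
  cat(sprintf("<mechano_report> %d gap elements\n", x$n_gap_elements))
  for (i in seq_len(nrow(x$zone_summary)))
    cat(sprintf("  %-32s %6d (%2d%%)\n", x$zone_summary$zone[i],
                x$zone_summary$count[i], x$zone_summary$percent[i]))
  cat(sprintf("  IFM axial %.4f mm, shear %.4f mm\n",
              x$ifm$axial_mm, x$ifm$shear_mm))
  for (i in seq_len(nrow(x$max_von_mises)))
    cat(sprintf("  max von Mises [%s] = %.1f MPa\n",
                x$max_von_mises$part[i], x$max_von_mises$max_von_mises[i]))
  invisible(x)
}
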