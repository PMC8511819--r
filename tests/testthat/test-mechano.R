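test_that("strain invariants match closed forms", {
  expect_equal(volumetric_strain(c(0.01, 0.01, 0.01, 0, 0, 0)), 0.03)
  expect_equal(volumetric_strain(c(0.01, -0.01, 0, 5, 5, 5)), 0)
  expect_equal(octahedral_shear_strain(c(0.02, 0.02, 0.02, 0, 0, 0)), 0,
               tolerance = 1e-14)
  # uniaxial eps = diag(0.01, 0, 0) -> (2/3) sqrt(2e-4)
  expect_equal(octahedral_shear_strain(c(0.01, 0, 0, 0, 0, 0)),
               (2 / 3) * sqrt(2e-4), tolerance = 1e-12)
  expect_equal(hydrostatic_pressure(c(-3, -3, -3, 0, 0, 0)), 3)
  expect_equal(hydrostatic_pressure(c(0, 0, 0, 9, 9, 9)), 0)   # pure shear
  expect_equal(hydrostatic_pressure(2.5 * c(-3, -3, -3, 0, 0, 0)), 2.5 * 3)
})

test_that("invariants are rotation invariant to 1e-10", {
  set.seed(5)
  for (rep_ in 1:25) {
    v <- random_symmetric_voigt()
    R <- random_rotation()
    vr <- rotate_voigt(v, R)
    expect_equal(octahedral_shear_strain(vr), octahedral_shear_strain(v),
                 tolerance = 1e-10)
    expect_equal(volumetric_strain(vr), volumetric_strain(v),
                 tolerance = 1e-10)
    # same tensors reused as stresses (non-engineering rotation)
    s <- tensor_to_voigt(matrix(c(v[1], v[4] / 2, v[6] / 2,
                                  v[4] / 2, v[2], v[5] / 2,
                                  v[6] / 2, v[5] / 2, v[3]), 3, 3),
                         engineering = FALSE)
    sr <- rotate_voigt(s, R, engineering = FALSE)
    expect_equal(hydrostatic_pressure(sr), hydrostatic_pressure(s),
                 tolerance = 1e-10)
    expect_equal(von_mises(sr), von_mises(s), tolerance = 1e-10)
  }
})

test_that("octahedral shear strain matches the deviator-invariant formula", {
  # gamma_oct = 2 sqrt(2 J2' / 3) with J2' = tr(dev^2)/2, on random tensors
  set.seed(17)
  for (rep_ in 1:1000) {
    v <- random_symmetric_voigt()
    eps <- matrix(c(v[1], v[4] / 2, v[6] / 2,
                    v[4] / 2, v[2], v[5] / 2,
                    v[6] / 2, v[5] / 2, v[3]), 3, 3)
    dev <- eps - diag(mean(diag(eps)), 3)
    j2 <- sum(dev * dev) / 2
    expect_equal(octahedral_shear_strain(v), 2 * sqrt(2 * j2 / 3),
                 tolerance = 1e-10)
  }
})

test_that("the default healing-zone rule classifies the reference cases", {
  rule <- healing_zone_rule()
  expect_equal(fracenv:::classify_points(0.02, 0.10, rule),
               "intramembranous_ossification")
  expect_equal(fracenv:::classify_points(0.40, 0.10, rule),
               "connective_tissue_excess")
  expect_equal(fracenv:::classify_points(0.40, 5, rule),
               "connective_tissue_excess")
  expect_equal(fracenv:::classify_points(0.10, 0.30, rule),
               "endochondral_ossification")
  expect_equal(fracenv:::classify_points(0.10, -0.30, rule),
               "connective_tissue_excess")  # tension beyond the limit
  expect_equal(fracenv:::classify_points(0, 0, rule), "resorption_band")
  rule2 <- healing_zone_rule(low_stimulus_band = FALSE)
  expect_equal(fracenv:::classify_points(0, 0, rule2),
               "intramembranous_ossification")
})

test_that("classify_elements is first-match deterministic and total", {
  rule <- healing_zone_rule()
  inv <- data.frame(gamma_oct = c(0.001, 0.04, 0.1, 0.2, 1),
                    p_hydro = c(0.01, 0.1, 0.2, 0.01, -3))
  got <- classify_elements(inv, rule)
  expect_equal(got, c("resorption_band", "intramembranous_ossification",
                      "endochondral_ossification", "connective_tissue_excess",
                      "connective_tissue_excess"))
  # scale-consistency: growing the load can only move elements to later zones
  order_of <- function(z) match(z, vapply(rule$zones, `[[`, "", "name"))
  for (f in c(2, 5, 20)) {
    scaled <- classify_elements(inv * f, rule)
    expect_true(all(order_of(scaled) >= order_of(got) |
                      scaled == "endochondral_ossification"))
  }
})

test_that("zone_fractions reproduces the headline-percent arithmetic", {
  labels <- c(rep("a", 20773), rep("b", 74977 - 20773))
  zf <- zone_fractions(labels)
  expect_equal(zf$count[zf$zone == "a"], 20773L)
  expect_equal(zf$fraction[zf$zone == "a"], 20773 / 74977, tolerance = 1e-12)
  expect_equal(zf$percent[zf$zone == "a"], 28)    # 27.7% -> "28 percent"
  expect_equal(sum(zf$fraction), 1, tolerance = 1e-12)
  one <- zone_fractions(rep("x", 10))
  expect_equal(one$percent, 100)
  set.seed(3)
  r <- zone_fractions(sample(letters[1:4], 500, TRUE))
  expect_equal(sum(r$fraction), 1, tolerance = 1e-12)
})

# bone | gap | bone sandwich for interfragmentary-movement tests
sandwich_mesh <- function() {
  codes <- fracenv_labels()
  lab <- array(codes[["bone"]], c(3, 3, 5))
  lab[, , 3] <- codes[["gap"]]
  voxels_to_tets(lab, spacing = c(1, 1, 1))
}

test_that("IFM recovers constructed rigid displacement fields", {
  mesh <- sandwich_mesh()
  gap_z_mid <- 2                         # gap voxel 3 spans z = 1.5 .. 2.5
  n <- nrow(mesh$nodes)
  # axial: proximal fragment moves down by 0.5 mm
  u <- matrix(0, n, 3)
  u[mesh$nodes[, 3] > gap_z_mid, 3] <- -0.5
  ifm <- interfragmentary_movement(list(displacement = u), mesh)
  expect_equal(ifm$axial_mm, 0.5, tolerance = 1e-12)
  expect_equal(ifm$shear_mm, 0, tolerance = 1e-12)
  # transverse: proximal fragment offsets by 0.2 mm in x
  u2 <- matrix(0, n, 3)
  u2[mesh$nodes[, 3] > gap_z_mid, 1] <- 0.2
  ifm2 <- interfragmentary_movement(list(displacement = u2), mesh)
  expect_equal(ifm2$axial_mm, 0, tolerance = 1e-12)
  expect_equal(ifm2$shear_mm, 0.2, tolerance = 1e-12)
  # zero displacement -> zero IFM
  ifm0 <- interfragmentary_movement(list(displacement = matrix(0, n, 3)), mesh)
  expect_equal(ifm0$axial_mm, 0)
  expect_equal(ifm0$shear_mm, 0)
})

test_that("IFM errors when the interfaces are not identifiable", {
  codes <- fracenv_labels()
  lab <- array(codes[["gap"]], c(2, 2, 2))  # no bone at all
  mesh <- voxels_to_tets(lab, spacing = c(1, 1, 1))
  u <- matrix(0, nrow(mesh$nodes), 3)
  expect_error(interfragmentary_movement(list(displacement = u), mesh),
               "not identifiable")
})

test_that("a non-covering rule is rejected at validation", {
  rule <- healing_zone_rule()
  rule$zones <- rule$zones[1:2]          # drop the catch-all
  expect_error(fracenv:::validate_zone_rule(rule), "does not cover")
  expect_error(classify_elements(data.frame(gamma_oct = 1, p_hydro = 1), rule),
               "does not cover")
})

test_that("mechano_report assembles a consistent summary", {
  mesh <- sandwich_mesh()
  mats <- assign_materials(
    mesh, image_volume(array(0.4, c(3, 3, 5)), spacing = c(1, 1, 1)))
  sol <- solve_elasticity(mesh, mats, load_case(force = c(5, 0, -40)))
  rep_ <- mechano_report(sol, mesh)
  expect_s3_class(rep_, "mechano_report")
  expect_equal(rep_$n_gap_elements, sum(mesh$part == fracenv_labels()[["gap"]]))
  expect_equal(sum(rep_$zone_summary$count), rep_$n_gap_elements)
  expect_equal(sum(rep_$zone_summary$fraction), 1, tolerance = 1e-12)
  expect_true(all(rep_$gap_zones %in%
                    vapply(rep_$rule$zones, `[[`, "", "name")))
  expect_match(rep_$sign_convention, "compression positive")
  expect_setequal(rep_$max_von_mises$part, c("bone", "gap"))
})
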