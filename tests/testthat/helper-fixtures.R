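# Shared fixtures, computed at most once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cache_once <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# Committed full-size treatment comparison (8 mm failed vs 9 mm revision).
scenario_reports <- function() {
  cache_once("scenario_reports", {
    pair <- scenario_pair(seed = 1L)
    list(failed = run_pipeline(pair$failed),
         revision = run_pipeline(pair$revision))
  })
}

# A reduced phantom that keeps every structural feature (cortex, trabecular
# ring, nail, screws, gap, rods) but solves in about a second.
small_phantom_overrides <- function() {
  list(volume_shape = c(36L, 36L, 22L),
       voxel_spacing = c(1.5, 1.5, 2.5),
       bone_z_range = c(6, 46),
       nail_z_range = c(10, 42),
       gap_center_mm = 26,
       screw_spec = data.frame(z_mm = c(14, 20, 32, 38), diameter_mm = 4))
}

small_scenario <- function(...) {
  # the reduced phantom has smaller bone fragments and rods than the
  # committed one, so the island filter needs a matching smaller cut-off
  scenario_config(name = "small", phantom = small_phantom_overrides(),
                  seg_params = segmentation_params(min_island_size = 200), ...)
}

# Hand-built single-region box mesh helpers -----------------------------------

# Labels for a solid box of nx x ny x nz voxels, all one part.
box_labels <- function(nx, ny, nz, code = fracenv_labels()[["bone"]]) {
  array(code, dim = c(nx, ny, nz))
}

# Homogeneous material table for a mesh (bypasses density sampling on purpose
# so solver tests control E and nu directly).
homogeneous_mats <- function(mesh, E, nu) {
  structure(data.frame(young_modulus = rep(E, nrow(mesh$elements)),
                       poisson_ratio = rep(nu, nrow(mesh$elements)),
                       ash_density = NA_real_,
                       tissue_class = "test",
                       stringsAsFactors = FALSE),
            class = c("material_field", "data.frame"))
}

# Voigt vector (engineering shear) of a symmetric 3x3 tensor.
tensor_to_voigt <- function(m, engineering = TRUE) {
  s <- if (engineering) 2 else 1
  c(m[1, 1], m[2, 2], m[3, 3], s * m[1, 2], s * m[2, 3], s * m[1, 3])
}

random_symmetric_voigt <- function() {
  a <- matrix(rnorm(9), 3, 3)
  tensor_to_voigt((a + t(a)) / 2)
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_voigt <- function(v, R, engineering = TRUE) {
  s <- if (engineering) 0.5 else 1
  m <- matrix(c(v[1], s * v[4], s * v[6],
                s * v[4], v[2], s * v[5],
                s * v[6], s * v[5], v[3]), 3, 3)
  tensor_to_voigt(R %*% m %*% t(R), engineering = engineering)
}
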