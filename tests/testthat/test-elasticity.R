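# Independent plain-R TET4 stiffness assembly used as an oracle.
r_tet4_stiffness <- function(nodes, elements, E, nu) {
  ndof <- 3 * nrow(nodes)
  K <- matrix(0, ndof, ndof)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  for (e in seq_len(nrow(elements))) {
    en <- elements[e, 1:4]
    X <- nodes[en, , drop = FALSE]
    M <- cbind(1, X)
    C <- solve(M)                      # gradients of shape fns in rows 2:4
    V <- abs(det(M)) / 6
    B <- matrix(0, 6, 12)
    for (i in 1:4) {
      g <- C[2:4, i]
      c0 <- 3 * (i - 1)
      B[1, c0 + 1] <- g[1]; B[2, c0 + 2] <- g[2]; B[3, c0 + 3] <- g[3]
      B[4, c0 + 1] <- g[2]; B[4, c0 + 2] <- g[1]
      B[5, c0 + 2] <- g[3]; B[5, c0 + 3] <- g[2]
      B[6, c0 + 1] <- g[3]; B[6, c0 + 3] <- g[1]
    }
    Ke <- V * t(B) %*% D %*% B
    dofs <- as.vector(t(outer(3 * (en - 1), 1:3, `+`)))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  K
}

test_that("load_case validates its force vector", {
  expect_error(load_case(force = c(1, 2)), "3 finite")
  expect_error(load_case(force = c(1, 2, NA)), "3 finite")
  expect_s3_class(load_case(), "load_case")
})

test_that("region selectors resolve faces, functions and indices", {
  mesh <- voxels_to_tets(box_labels(2, 2, 2), spacing = c(1, 1, 1))
  lo <- fracenv:::resolve_region(mesh, "z_min")
  hi <- fracenv:::resolve_region(mesh, "z_max")
  expect_equal(length(lo), 9)
  expect_equal(length(hi), 9)
  expect_true(all(mesh$nodes[lo, 3] == min(mesh$nodes[, 3])))
  fn <- fracenv:::resolve_region(mesh, function(n) n[, 1] > 1)
  expect_true(all(mesh$nodes[fn, 1] > 1))
  expect_equal(fracenv:::resolve_region(mesh, c(3L, 5L)), c(3L, 5L))
  expect_error(fracenv:::resolve_region(mesh, "y_max"), "unknown region")
  expect_error(fracenv:::resolve_region(mesh, function(n) n[, 1] > 99),
               "empty node region")
})

test_that("assembled stiffness matches an independent R assembly", {
  mesh <- voxels_to_tets(box_labels(1, 1, 1), spacing = c(1, 1.2, 0.8))
  mats <- homogeneous_mats(mesh, E = 2500, nu = 0.27)
  K <- as.matrix(assemble_stiffness(mesh, mats))
  K_r <- r_tet4_stiffness(mesh$nodes, mesh$elements, 2500, 0.27)
  expect_equal(K, K_r, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(K, t(K), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("rigid-body motions lie in the stiffness nullspace", {
  for (order in 1:2) {
    mesh <- voxels_to_tets(box_labels(2, 2, 2), spacing = c(1, 1, 1),
                           order = order)
    mats <- homogeneous_mats(mesh, E = 1000, nu = 0.3)
    K <- assemble_stiffness(mesh, mats)
    scale <- max(abs(K))
    # three translations
    for (k in 1:3) {
      u <- matrix(0, nrow(mesh$nodes), 3); u[, k] <- 1
      expect_lt(max(abs(K %*% as.vector(t(u)))), 1e-9 * scale)
    }
    # three infinitesimal rotations u = w x x
    for (k in 1:3) {
      w <- c(0, 0, 0); w[k] <- 1
      u <- t(apply(mesh$nodes, 1, function(x)
        c(w[2] * x[3] - w[3] * x[2], w[3] * x[1] - w[1] * x[3],
          w[1] * x[2] - w[2] * x[1])))
      expect_lt(max(abs(K %*% as.vector(t(u)))), 1e-8 * scale)
    }
  }
})

test_that("inverted elements are rejected with the element named", {
  mesh <- voxels_to_tets(box_labels(1, 1, 1), spacing = c(1, 1, 1))
  bad <- mesh
  bad$nodes <- -bad$nodes               # mirrors every tet
  mats <- homogeneous_mats(mesh, 1000, 0.3)
  expect_error(assemble_stiffness(bad, mats), "inverted element")
})

test_that("uniaxial bar matches u = FL/EA for TET4 and TET10", {
  for (order in 1:2) {
    mesh <- voxels_to_tets(box_labels(2, 2, 8), spacing = c(1, 1, 1),
                           order = order)
    mats <- homogeneous_mats(mesh, E = 1000, nu = 0)
    lc <- load_case(force = c(0, 0, -100), distribution = "traction")
    sol <- solve_elasticity(mesh, mats, lc)
    tip <- fracenv:::resolve_region(mesh, "z_max")
    u_exact <- -100 * 8 / (1000 * 4)    # FL/EA = -0.2 mm
    expect_equal(max(abs(sol$displacement[tip, 3] - u_exact)), 0,
                 tolerance = 1e-10 * abs(u_exact))
    expect_equal(max(abs(sol$strain[, "ezz"] + 0.025)), 0, tolerance = 1e-12)
    expect_lt(max(abs(sol$strain[, "exx"])), 1e-12)
    expect_equal(max(abs(sol$stress[, "szz"] + 25)), 0, tolerance = 1e-9)
    expect_lt(sol$diagnostics$equilibrium_residual, 1e-6)
    expect_equal(unname(sol$von_mises), rep(25, nrow(mesh$elements)),
                 tolerance = 1e-10)
  }
})

test_that("the solution is linear in the load and inverse in the modulus", {
  mesh <- voxels_to_tets(box_labels(2, 2, 4), spacing = c(1, 1, 1))
  lc1 <- load_case(force = c(30, 0, -100))
  lc2 <- load_case(force = c(60, 0, -200))
  m1 <- homogeneous_mats(mesh, 1000, 0.3)
  m2 <- homogeneous_mats(mesh, 2000, 0.3)
  s11 <- solve_elasticity(mesh, m1, lc1)
  s12 <- solve_elasticity(mesh, m1, lc2)
  s21 <- solve_elasticity(mesh, m2, lc1)
  expect_equal(s12$displacement, 2 * s11$displacement, tolerance = 1e-9)
  expect_equal(s21$displacement, s11$displacement / 2, tolerance = 1e-9)
  expect_equal(s12$stress, 2 * s11$stress, tolerance = 1e-9)
  expect_equal(s21$stress, s11$stress, tolerance = 1e-9)  # stress is E-free here
})

test_that("zero force gives the zero solution", {
  mesh <- voxels_to_tets(box_labels(2, 2, 3), spacing = c(1, 1, 1))
  mats <- homogeneous_mats(mesh, 1000, 0.3)
  sol <- solve_elasticity(mesh, mats, load_case(force = c(0, 0, 0)))
  expect_equal(max(abs(sol$displacement)), 0)
  expect_equal(max(abs(sol$von_mises)), 0)
})

test_that("TET4 passes the affine patch test exactly", {
  mesh <- voxels_to_tets(box_labels(2, 2, 2), spacing = c(1, 1, 1))
  A <- matrix(c(2, 1, -1, 0.5, -3, 2.5, 1.5, -0.5, 1), 3, 3) * 1e-3
  on_boundary <- function(n) {
    lo <- apply(n, 2, min); hi <- apply(n, 2, max)
    apply(n, 1, function(x) any(abs(x - lo) < 1e-9 | abs(x - hi) < 1e-9))
  }
  boundary <- which(on_boundary(mesh$nodes))
  interior <- setdiff(seq_len(nrow(mesh$nodes)), boundary)
  expect_equal(length(interior), 1)
  lc <- load_case(force = c(0, 0, 0), fixed_region = boundary,
                  load_region = interior,
                  prescribed = function(n) n %*% t(A))
  mats <- homogeneous_mats(mesh, 1200, 0.32)
  sol <- solve_elasticity(mesh, mats, lc)
  u_exact <- mesh$nodes %*% t(A)
  expect_equal(max(abs(sol$displacement - u_exact)), 0, tolerance = 1e-12)
  sym <- (A + t(A)) / 2
  eps_exact <- c(sym[1, 1], sym[2, 2], sym[3, 3],
                 2 * sym[1, 2], 2 * sym[2, 3], 2 * sym[1, 3])
  for (k in 1:6)
    expect_equal(unname(sol$strain[, k]), rep(eps_exact[k], nrow(mesh$elements)),
                 tolerance = 1e-10)
})

test_that("von Mises matches closed forms", {
  expect_equal(von_mises(c(100, 0, 0, 0, 0, 0)), 100)
  expect_equal(von_mises(c(-50, -50, -50, 0, 0, 0)), 0)    # hydrostatic
  expect_equal(von_mises(c(0, 0, 0, 10, 0, 0)), sqrt(3) * 10)
  expect_equal(von_mises(c(0, 0, 0, 0, 7, 0)), sqrt(3) * 7)
  m <- rbind(c(100, 0, 0, 0, 0, 0), c(0, 0, 0, 10, 0, 0))
  expect_equal(von_mises(m), c(100, sqrt(3) * 10))
})

test_that("per-part maxima agree with a direct scan, lowest id wins ties", {
  codes <- fracenv_labels()
  lab <- array(codes[["bone"]], c(2, 1, 2))
  lab[, , 2] <- codes[["gap"]]
  mesh <- voxels_to_tets(lab, spacing = c(1, 1, 1))
  ne <- nrow(mesh$elements)
  set.seed(9)
  vm <- runif(ne)
  vm[mesh$part == codes[["gap"]]][1] <- 2   # not assigned back; keep scan honest
  sol <- list(von_mises = vm)
  out <- max_von_mises_by_part(sol, mesh)
  for (p in unique(mesh$part)) {
    nm <- names(codes)[match(p, codes)]
    expect_equal(out$max_von_mises[out$part == nm], max(vm[mesh$part == p]))
  }
  # tie-break: duplicate maximum takes the lowest element id
  vm2 <- rep(1, ne)
  out2 <- max_von_mises_by_part(list(von_mises = vm2), mesh)
  for (nm in out2$part) {
    p <- codes[[nm]]
    expect_equal(out2$element[out2$part == nm], min(which(mesh$part == p)))
  }
})

test_that("overlapping fixed and load regions are rejected", {
  mesh <- voxels_to_tets(box_labels(1, 1, 1), spacing = c(1, 1, 1))
  mats <- homogeneous_mats(mesh, 1000, 0.3)
  lc <- load_case(force = c(0, 0, 1), fixed_region = 1:8, load_region = 4:8)
  expect_error(solve_elasticity(mesh, mats, lc), "disjoint")
})
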