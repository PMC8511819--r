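#' Define a load case
#'
#' A load case fixes one node region (homogeneous or prescribed Dirichlet
#' conditions) and distributes a total force vector over another. Units: N.
#'
#' @param force Length-3 total force vector (N) applied over `load_region`.
#' @param fixed_region,load_region Node selectors: `"z_min"` / `"z_max"`, a
#'   function of the node coordinate matrix returning a logical vector, or an
#'   integer vector of node indices.
#' @param distribution `"uniform"` (equal share per node) or `"traction"`
#'   (consistent nodal loads for a uniform traction over the region's
#'   boundary faces; exact for patch-type solutions).
#' @param prescribed Optional function of the node coordinate matrix
#'   returning an n x 3 displacement matrix imposed on `fixed_region`
#'   (defaults to zero displacement).
#' @param description Free-text description of the load case.
#' @return A `load_case` list.
#' @export
load_case <- function(force = c(0, 0, 0), fixed_region = "z_min",
                      load_region = "z_max", distribution = c("uniform", "traction"),
                      prescribed = NULL, description = "") {
  force <- as.numeric(force)
  if (length(force) != 3L || any(!is.finite(force))) stop("force must be 3 finite values (N)")
  structure(list(force = force, fixed_region = fixed_region,
                 load_region = load_region,
                 distribution = match.arg(distribution),
                 prescribed = prescribed, description = description),
            class = "load_case")
}

resolve_region <- function(mesh, sel, tol = 1e-8) {
  nodes <- mesh$nodes
  if (is.character(sel)) {
    z <- nodes[, 3]
    idx <- switch(sel,
                  z_min = which(z <= min(z) + tol),
                  z_max = which(z >= max(z) - tol),
                  stop("unknown region selector: ", sel))
  } else if (is.function(sel)) {
    idx <- which(sel(nodes))
  } else {
    idx <- as.integer(sel)
  }
  if (length(idx) == 0L) stop("empty node region")
  idx
}

#' Assemble the global stiffness matrix
#'
#' Symmetric sparse stiffness operator for small-strain isotropic linear
#' elasticity; single-point integration for TET4, 4-point Gauss for TET10
#' (exact for straight-edge quadratic tetrahedra). Inverted elements
#' (non-positive Jacobian) raise an error naming the element.
#'
#' @param mesh A `tet_mesh`.
#' @param mats A `material_field` with one row per element.
#' @return A `dgCMatrix`/`dsCMatrix` of dimension `3n x 3n` (DOF order
#'   x1,y1,z1,x2,...), symmetric.
#' @export
assemble_stiffness <- function(mesh, mats) {
  if (nrow(mats) != nrow(mesh$elements))
    stop("materials must be assigned to every element")
  tr <- cpp_assemble(mesh$nodes, mesh$elements, mats$young_modulus,
                     mats$poisson_ratio, mesh$order)
  ndof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                            dims = c(ndof, ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

boundary_faces <- function(mesh) {
  el <- mesh$elements
  corner_faces <- list(c(1, 2, 3), c(1, 2, 4), c(2, 3, 4), c(1, 3, 4))
  mid_faces <- list(c(5, 6, 7), c(5, 9, 8), c(6, 10, 9), c(7, 10, 8))
  faces <- do.call(rbind, lapply(corner_faces, function(f) el[, f, drop = FALSE]))
  key <- apply(faces, 1, function(r) paste(sort(r), collapse = "-"))
  once <- names(which(table(key) == 1L))
  sel <- key %in% once
  out <- faces[sel, , drop = FALSE]
  if (mesh$order == 2) {
    mids <- do.call(rbind, lapply(mid_faces, function(f) el[, f, drop = FALSE]))
    out <- cbind(out, mids[sel, , drop = FALSE])
  }
  out
}

load_vector <- function(mesh, lc, load_idx) {
  ndof <- 3L * nrow(mesh$nodes)
  f <- numeric(ndof)
  if (all(lc$force == 0)) return(f)
  if (lc$distribution == "uniform") {
    share <- lc$force / length(load_idx)
    for (k in 1:3) f[3 * (load_idx - 1) + k] <- share[k]
    return(f)
  }
  # consistent nodal loads for uniform traction over the region's boundary faces
  bf <- boundary_faces(mesh)
  in_region <- matrix(bf %in% load_idx, nrow = nrow(bf))
  keep <- rowSums(in_region) == ncol(bf)
  bf <- bf[keep, , drop = FALSE]
  if (nrow(bf) == 0L) stop("no boundary faces found inside the load region")
  w <- numeric(nrow(mesh$nodes))
  for (r in seq_len(nrow(bf))) {
    tri <- mesh$nodes[bf[r, 1:3], ]
    area <- 0.5 * sqrt(sum(crossprod_vec(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])^2))
    if (mesh$order == 2) {
      # quadratic triangle under constant traction: corners 0, midsides A/3
      for (m in 4:6) w[bf[r, m]] <- w[bf[r, m]] + area / 3
    } else {
      for (m in 1:3) w[bf[r, m]] <- w[bf[r, m]] + area / 3
    }
  }
  wn <- w / sum(w)
  nz <- which(wn != 0)
  for (k in 1:3) f[3 * (nz - 1) + k] <- wn[nz] * lc$force[k]
  f
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Solve the constrained linear-elastic system
#'
#' Direct sparse Cholesky factorization below 2e5 free DOF, Jacobi
#' preconditioned conjugate gradients above (relative tolerance 1e-8).
#' Returns nodal displacements, per-element strain and stress tensors
#' (element average over integration points), von Mises stress, and solver
#' diagnostics including the global equilibrium check.
#'
#' @param mesh A `tet_mesh`.
#' @param mats A `material_field`.
#' @param lc A [load_case()].
#' @param K Optional pre-assembled stiffness from [assemble_stiffness()].
#' @return A `field_solution` list: `displacement` (n x 3 mm), `strain`
#'   (ne x 6 Voigt, engineering shear), `stress` (ne x 6 MPa), `von_mises`
#'   (ne MPa), `diagnostics`.
#' @export
solve_elasticity <- function(mesh, mats, lc, K = NULL) {
  if (is.null(K)) K <- assemble_stiffness(mesh, mats)
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  fixed_idx <- resolve_region(mesh, lc$fixed_region)
  load_idx <- resolve_region(mesh, lc$load_region)
  if (length(intersect(fixed_idx, load_idx)))
    stop("fixed and load regions must be disjoint")

  fixed_dofs <- as.vector(t(outer(3 * (fixed_idx - 1), 1:3, `+`)))
  free_dofs <- setdiff(seq_len(ndof), fixed_dofs)
  if (length(free_dofs) == 0L) stop("no free degrees of freedom")

  u <- numeric(ndof)
  if (!is.null(lc$prescribed)) {
    up <- lc$prescribed(mesh$nodes[fixed_idx, , drop = FALSE])
    u[fixed_dofs] <- as.vector(t(up))
  }

  f <- load_vector(mesh, lc, load_idx)
  rhs <- f[free_dofs] - as.numeric(K[free_dofs, fixed_dofs, drop = FALSE] %*%
                                     u[fixed_dofs])
  Kff <- K[free_dofs, free_dofs, drop = FALSE]

  if (length(free_dofs) <= 2e5) {
    uf <- as.numeric(Matrix::solve(Kff, rhs))
    method <- "direct sparse Cholesky"
    iters <- NA_integer_
  } else {
    cg <- pcg_solve(Kff, rhs, tol = 1e-8)
    uf <- cg$x
    method <- "Jacobi-preconditioned CG"
    iters <- cg$iterations
  }
  u[free_dofs] <- uf

  rnorm_ <- sqrt(sum((as.numeric(Kff %*% uf) - rhs)^2))
  rel_res <- if (sqrt(sum(rhs^2)) > 0) rnorm_ / sqrt(sum(rhs^2)) else rnorm_
  if (is.finite(rel_res) && rel_res > 1e-8 && sqrt(sum(rhs^2)) > 0)
    warning(sprintf("relative residual %.3g exceeds 1e-8", rel_res))

  full_res <- as.numeric(K %*% u) - f
  reactions <- full_res[fixed_dofs]
  applied <- vapply(1:3, function(k) sum(f[seq(k, ndof, by = 3)]), 0)
  reac_sum <- vapply(1:3, function(k)
    sum(full_res[fixed_dofs[(fixed_dofs - 1) %% 3 + 1 == k]]), 0)
  balance <- sqrt(sum((applied + reac_sum)^2))
  balance_rel <- if (sqrt(sum(applied^2)) > 0) balance / sqrt(sum(applied^2)) else balance

  fields <- cpp_element_fields(mesh$nodes, mesh$elements, mats$young_modulus,
                               mats$poisson_ratio, u, mesh$order)
  strain <- fields[, 1:6, drop = FALSE]
  stress <- fields[, 7:12, drop = FALSE]
  colnames(strain) <- c("exx", "eyy", "ezz", "gxy", "gyz", "gxz")
  colnames(stress) <- c("sxx", "syy", "szz", "sxy", "syz", "sxz")

  structure(list(
    displacement = matrix(u, ncol = 3, byrow = TRUE,
                          dimnames = list(NULL, c("ux", "uy", "uz"))),
    strain = strain, stress = stress,
    von_mises = von_mises(stress),
    diagnostics = list(method = method, iterations = iters,
                       relative_residual = rel_res,
                       equilibrium_residual = balance_rel,
                       n_free_dofs = length(free_dofs),
                       applied_force = applied,
                       reaction_force = reac_sum)),
    class = "field_solution")
}

pcg_solve <- function(A, b, tol = 1e-8, maxit = 20000L) {
  Minv <- 1 / Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * bnorm) break
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iterations = it)
}

#' Von Mises equivalent stress
#'
#' `sqrt(3 J2)` of the stress deviator, from Voigt stress components
#' (xx, yy, zz, xy, yz, xz).
#'
#' @param sigma Length-6 vector or ne x 6 matrix of stresses (MPa).
#' @return Von Mises stress (MPa), one value per row.
#' @export
von_mises <- function(sigma) {
  if (is.null(dim(sigma))) sigma <- matrix(sigma, nrow = 1)
  sqrt(0.5 * ((sigma[, 1] - sigma[, 2])^2 + (sigma[, 2] - sigma[, 3])^2 +
                (sigma[, 3] - sigma[, 1])^2) +
         3 * (sigma[, 4]^2 + sigma[, 5]^2 + sigma[, 6]^2))
}

#' Maximum von Mises stress per mesh part
#'
#' @param sol A `field_solution`.
#' @param mesh The `tet_mesh` the solution was computed on.
#' @return data.frame with `part` (label name), `max_von_mises` (MPa) and
#'   `element` (id of the maximizing element; lowest id wins ties). Parts
#'   without elements are absent.
#' @export
max_von_mises_by_part <- function(sol, mesh) {
  codes <- fracenv_labels()
  name_of <- setNames(names(codes), codes)
  parts <- sort(unique(mesh$part))
  rows <- lapply(parts, function(p) {
    idx <- which(mesh$part == p)
    vm <- sol$von_mises[idx]
    best <- which.max(vm)  # which.max returns the first (lowest id) maximum
    data.frame(part = unname(name_of[as.character(p)]),
               max_von_mises = vm[best], element = idx[best])
  })
  do.call(rbind, rows)
}
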