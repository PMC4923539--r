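# local corner signs matching the VTK hexahedron node order used in
# voxels_to_hexmesh: (xi, eta, zeta) in {-1, 1}
HEX_SIGNS <- matrix(c(-1, -1, -1, 1, -1, -1, 1, 1, -1, -1, 1, -1,
                      -1, -1, 1, 1, -1, 1, 1, 1, 1, -1, 1, 1),
                    ncol = 3, byrow = TRUE)

# isotropic elasticity matrix, Voigt order (xx, yy, zz, xy, yz, xz) with
# engineering shear strains
elasticity_matrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

#' Stiffness matrix of a cubic 8-node hexahedral element
#'
#' Standard trilinear isoparametric stiffness with 2x2x2 Gauss quadrature and
#' the isotropic elasticity tensor from `(E, nu)`. DOF ordering: (ux, uy, uz)
#' per node, nodes in the VTK hexahedron corner order. Because the element is
#' a cube of side `h`, the Jacobian is diagonal and the matrix scales linearly
#' in both `E` and `h`.
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param h element (voxel) side, mm.
#' @return a 24 x 24 symmetric positive-semidefinite matrix.
#' @export
hex_stiffness <- function(E, nu, h) {
  stopifnot(E > 0, h > 0)
  if (nu <= 0 || nu >= 0.5) stop("nu must lie strictly in (0, 0.5)")
  D <- elasticity_matrix(E, nu)
  gp <- 1 / sqrt(3)
  K <- matrix(0, 24, 24)
  detJ <- (h / 2)^3
  for (g1 in c(-gp, gp)) for (g2 in c(-gp, gp)) for (g3 in c(-gp, gp)) {
    # dN/dx = (2/h) * dN/dxi etc.
    dN <- cbind(
      HEX_SIGNS[, 1] * (1 + HEX_SIGNS[, 2] * g2) * (1 + HEX_SIGNS[, 3] * g3),
      (1 + HEX_SIGNS[, 1] * g1) * HEX_SIGNS[, 2] * (1 + HEX_SIGNS[, 3] * g3),
      (1 + HEX_SIGNS[, 1] * g1) * (1 + HEX_SIGNS[, 2] * g2) * HEX_SIGNS[, 3]
    ) / 8 * (2 / h)
    B <- matrix(0, 6, 24)
    ix <- seq(1, 24, by = 3)
    B[1, ix] <- dN[, 1]
    B[2, ix + 1] <- dN[, 2]
    B[3, ix + 2] <- dN[, 3]
    B[4, ix] <- dN[, 2]; B[4, ix + 1] <- dN[, 1]
    B[5, ix + 1] <- dN[, 3]; B[5, ix + 2] <- dN[, 2]
    B[6, ix] <- dN[, 3]; B[6, ix + 2] <- dN[, 1]
    K <- K + t(B) %*% D %*% B * detJ
  }
  (K + t(K)) / 2
}

#' Jacobi-preconditioned conjugate gradient
#'
#' @param A symmetric positive-definite sparse matrix.
#' @param b right-hand side.
#' @param tol relative-residual tolerance.
#' @param maxiter iteration cap.
#' @param x0 optional initial guess.
#' @return list with `x`, `iterations`, `relative_residual`, `converged`.
#' @keywords internal
pcg_solve <- function(A, b, tol = 1e-8, maxiter = 20000L, x0 = NULL) {
  n <- length(b)
  Minv <- 1 / Matrix::diag(A)
  if (any(!is.finite(Minv))) stop("singular system: zero diagonal entry")
  nb <- sqrt(sum(b^2))
  if (nb == 0) {
    return(list(x = numeric(n), iterations = 0L, relative_residual = 0,
                converged = TRUE))
  }
  x <- if (is.null(x0)) numeric(n) else x0
  r <- b - as.numeric(A %*% x)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  it <- 0L
  relres <- sqrt(sum(r^2)) / nb
  while (relres > tol && it < maxiter) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r^2)) / nb
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
    it <- it + 1L
  }
  list(x = x, iterations = it, relative_residual = relres,
       converged = relres <= tol)
}

#' Assemble and solve the linear-elastic equilibrium problem
#'
#' Assembles the global stiffness matrix (one cached element template per
#' distinct material, since all voxels share one spacing), eliminates the
#' constrained DOFs by reduction, and solves the remaining symmetric
#' positive-definite system with Jacobi-preconditioned conjugate gradients
#' (default) or a sparse Cholesky direct solve. Prescribed displacements
#' (including non-zero values via `bcs$constraints$value`) are honoured
#' exactly; reaction forces at constrained DOFs are recovered from the full
#' residual.
#'
#' @param mesh a `hex_mesh` with materials assigned.
#' @param bcs a `boundary_conditions` object from [build_bcs()], or any list
#'   with a `constraints` data frame (node, comp, value) and optionally a
#'   `force` N x 3 matrix.
#' @param tol PCG relative-residual tolerance (default 1e-8).
#' @param maxiter PCG iteration cap.
#' @param method `"pcg"` or `"direct"`.
#' @return a list of class `fe_solution`: `u` (N x 3 displacement, mm, exact
#'   zeros/prescribed values at constrained DOFs), `report` (iterations,
#'   relative_residual, converged, dof_count), `reactions` (data frame of
#'   constrained DOF reactions, N) and `applied` (total applied force).
#' @export
assemble_and_solve <- function(mesh, bcs, tol = 1e-8, maxiter = 20000L,
                               method = c("pcg", "direct")) {
  stopifnot(inherits(mesh, "hex_mesh"))
  if (is.null(mesh$E)) stop("assign materials before solving")
  method <- match.arg(method)
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn

  K <- assemble_stiffness(mesh)

  f <- numeric(ndof)
  if (!is.null(bcs$force)) {
    f[seq(1, ndof, by = 3)] <- bcs$force[, 1]
    f[seq(2, ndof, by = 3)] <- bcs$force[, 2]
    f[seq(3, ndof, by = 3)] <- bcs$force[, 3]
  }
  cons <- bcs$constraints
  if (is.null(cons) || nrow(cons) == 0L) stop("fixed DOF set must be nonempty")
  cdof <- 3L * (cons$node - 1L) + cons$comp
  if (anyDuplicated(cdof)) {
    keep <- !duplicated(cdof)
    cons <- cons[keep, , drop = FALSE]
    cdof <- cdof[keep]
  }
  free <- setdiff(seq_len(ndof), cdof)
  uc <- cons$value
  rhs <- f[free]
  if (any(uc != 0)) {
    rhs <- rhs - as.numeric(K[free, cdof, drop = FALSE] %*% uc)
  }
  Kff <- K[free, free, drop = FALSE]
  if (method == "pcg") {
    sol <- pcg_solve(Kff, rhs, tol = tol, maxiter = maxiter)
    if (!sol$converged) {
      warning(sprintf(
        "PCG did not converge in %d iterations (relative residual %.3e); %s",
        sol$iterations, sol$relative_residual,
        "check for floating (unconstrained) components"))
    }
  } else {
    x <- as.numeric(Matrix::solve(Matrix::forceSymmetric(Kff), rhs))
    sol <- list(x = x, iterations = NA_integer_,
                relative_residual = sqrt(sum((rhs - as.numeric(Kff %*% x))^2)) /
                  max(sqrt(sum(rhs^2)), .Machine$double.xmin),
                converged = TRUE)
  }
  ufull <- numeric(ndof)
  ufull[free] <- sol$x
  ufull[cdof] <- uc
  resid <- as.numeric(K %*% ufull) - f
  reactions <- data.frame(node = cons$node, comp = cons$comp,
                          force_N = resid[cdof])
  u <- matrix(ufull, ncol = 3L, byrow = TRUE)
  structure(
    list(u = u,
         report = list(iterations = sol$iterations,
                       relative_residual = sol$relative_residual,
                       converged = sol$converged,
                       dof_count = length(free)),
         reactions = reactions,
         applied = colSums(matrix(f, ncol = 3L, byrow = TRUE))),
    class = "fe_solution"
  )
}

# global stiffness from per-material cached element templates
assemble_stiffness <- function(mesh) {
  nn <- nrow(mesh$nodes)
  ndof <- 3L * nn
  mat_key <- paste(mesh$E, mesh$nu, sep = "_")
  groups <- split(seq_len(nrow(mesh$elems)), mat_key)
  ii <- vector("list", length(groups))
  jj <- vector("list", length(groups))
  xx <- vector("list", length(groups))
  for (gI in seq_along(groups)) {
    els <- groups[[gI]]
    Ke <- hex_stiffness(mesh$E[els[1]], mesh$nu[els[1]], mesh$h)
    conn <- mesh$elems[els, , drop = FALSE]
    edof <- matrix(0L, length(els), 24L)
    edof[, seq(1, 24, 3)] <- 3L * (conn - 1L) + 1L
    edof[, seq(2, 24, 3)] <- 3L * (conn - 1L) + 2L
    edof[, seq(3, 24, 3)] <- 3L * conn
    ii[[gI]] <- as.vector(edof[, rep(1:24, times = 24), drop = FALSE])
    jj[[gI]] <- as.vector(edof[, rep(1:24, each = 24), drop = FALSE])
    xx[[gI]] <- rep(as.vector(Ke), each = length(els))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(ndof, ndof))
}

#' @export
print.fe_solution <- function(x, ...) {
  r <- x$report
  cat("<fe_solution> ", r$dof_count, " free DOF; ",
      if (is.na(r$iterations)) "direct solve" else
        paste0("PCG ", r$iterations, " iterations"),
      ", relative residual ", signif(r$relative_residual, 3),
      if (r$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  invisible(x)
}
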