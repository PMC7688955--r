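#' Material property field
#'
#' Maps tissue labels to linear-elastic properties: Young's modulus E of
#' 2 / 4 / 20 kPa for adipose / fibroglandular / tumor, Poisson ratio nu,
#' and the shear modulus G = E / (2 (1 - nu)) used by the equilibrium
#' equation.
#'
#' @param domain a [breast_domain()].
#' @param config a [study_config()] supplying `E_*`, `nu`, and `lambda`.
#' @return a `material_field`: arrays `E`, `G`, `kappa` (= G / (1 - 2 nu))
#'   plus scalars `nu`, `lambda`.
#' @export
material_field <- function(domain, config = study_config()) {
  lab <- domain$tissue_labels
  E <- array(0, dim(lab))
  E[lab == 1L] <- config$E_adipose
  E[lab == 2L] <- config$E_fibroglandular
  E[lab == 3L] <- config$E_tumor
  nu <- config$nu
  if (nu >= 0.5) stop("Poisson ratio must be < 0.5")
  G <- E / (2 * (1 - nu))
  structure(list(E = E, G = G, kappa = G / (1 - 2 * nu),
                 nu = nu, lambda = config$lambda),
            class = "material_field")
}

# Sparse central-difference operator d/dx_axis over in-mask voxels with
# Dirichlet u = 0 ghost nodes outside the mask (and outside the grid).
# `idx` is an integer array: 0 outside the solve set, 1..n inside.
central_diff_op <- function(idx, axis, h) {
  n <- max(idx)
  d <- dim(idx)
  if (d[axis] == 1L) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                 x = numeric(0), dims = c(n, n)))
  plus <- shift3(idx, axis, +1, fill = 0L)   # neighbor at i+1
  minus <- shift3(idx, axis, -1, fill = 0L)  # neighbor at i-1
  here <- which(idx > 0L)
  rows <- idx[here]
  ii <- c(rows[plus[here] > 0L], rows[minus[here] > 0L])
  jj <- c(plus[here][plus[here] > 0L], minus[here][minus[here] > 0L])
  xx <- c(rep(1 / (2 * h), sum(plus[here] > 0L)),
          rep(-1 / (2 * h), sum(minus[here] > 0L)))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

# Variable-coefficient compact Laplacian sum over `axes` of
# d/dx_a (G d/dx_a .) with face-averaged G and Dirichlet u = 0 ghosts at
# the mask boundary.
laplacian_op <- function(idx, G, spacing, axes = 1:3) {
  n <- max(idx)
  d <- dim(idx)
  iL <- jL <- integer(0); xL <- numeric(0)
  diagv <- numeric(n)
  here <- which(idx > 0L)
  rows <- idx[here]
  for (axis in axes) {
    if (d[axis] == 1L) next
    h2 <- spacing[axis]^2
    for (dir in c(+1, -1)) {
      nb <- shift3(idx, axis, dir, fill = 0L)
      Gnb <- shift3(G, axis, dir, fill = NA)
      gface <- ifelse(nb[here] > 0L, (G[here] + Gnb[here]) / 2, G[here])
      # off-diagonal entries only for in-set neighbors; ghosts contribute
      # -gface/h2 to the diagonal with u_ghost = 0
      has <- nb[here] > 0L
      iL <- c(iL, rows[has]); jL <- c(jL, nb[here][has])
      xL <- c(xL, gface[has] / h2)
      diagv[rows] <- diagv[rows] - gface / h2
    }
  }
  Matrix::sparseMatrix(i = c(iL, seq_len(n)), j = c(jL, seq_len(n)),
                       x = c(xL, diagv), dims = c(n, n))
}

#' Assemble (and factorize) the elastic equilibrium operator
#'
#' Builds the sparse finite-difference operator of the mechanical
#' equilibrium `div(G grad u) + grad[(G/(1-2 nu)) div u] = lambda grad N`
#' over in-mask voxels with zero-displacement (rigid surroundings) ghost
#' nodes at the breast boundary, and caches its LU factorization. The
#' factorization depends only on the material field, so it is reused across
#' time steps and optimizer iterations.
#'
#' @param materials a [material_field()].
#' @param domain a [breast_domain()].
#' @param spacing voxel spacing in mm.
#' @return an `elastic_operator` for [solve_equilibrium()].
#' @export
elastic_operator <- function(materials, domain, spacing) {
  mask <- domain$mask
  idx <- array(0L, dim(mask))
  idx[mask] <- seq_len(sum(mask))
  n <- sum(mask)
  Dc <- lapply(1:3, function(a) central_diff_op(idx, a, spacing[a]))
  Kap <- Matrix::Diagonal(n, x = materials$kappa[mask])
  Lap <- laplacian_op(idx, materials$G, spacing)
  # diagonal part of grad(kappa div u) discretized compactly (face-averaged
  # kappa), mixed derivatives by composed central differences; this keeps
  # second order while avoiding the wide-stencil checkerboard modes
  blocks <- vector("list", 3L)
  for (l in 1:3) {
    row <- vector("list", 3L)
    for (a in 1:3) {
      if (l == a)
        row[[a]] <- Lap + laplacian_op(idx, materials$kappa, spacing, axes = l)
      else
        row[[a]] <- Dc[[l]] %*% Kap %*% Dc[[a]]
    }
    blocks[[l]] <- do.call(cbind, row)
  }
  K <- do.call(rbind, blocks)
  # K is symmetric negative definite (elastic energy); factor -K by sparse
  # Cholesky with fill-reducing permutation and solve -K u = -rhs
  chol <- Matrix::Cholesky(Matrix::forceSymmetric(-K), LDL = FALSE, perm = TRUE)
  structure(list(chol = chol, idx = idx, Dc = Dc, n = n, spacing = spacing,
                 materials = materials, mask = mask),
            class = "elastic_operator")
}

#' Solve the mechanical equilibrium
#'
#' Computes the tissue displacement driven by tumor-cell gradients and the
#' resulting von Mises stress. The forcing is `lambda * grad N_TC`; uniform
#' cellularity or `lambda = 0` therefore gives zero displacement and stress.
#' Stress is recovered from the strain field by linear isotropic elasticity
#' with the same G and nu.
#'
#' @param n_tc a [cellularity_map()] (or `image_volume` of counts).
#' @param materials a [material_field()].
#' @param domain a [breast_domain()].
#' @param spacing voxel spacing (mm); taken from `n_tc` when available.
#' @param op optional pre-built [elastic_operator()] (cached factorization).
#' @return a `mechanical_state`: displacement arrays `u` (list of 3, mm) and
#'   `von_mises` (kPa).
#' @export
solve_equilibrium <- function(n_tc, materials, domain, spacing = NULL,
                              op = NULL) {
  counts <- if (inherits(n_tc, "cellularity_map")) n_tc$counts
            else if (is_image_volume(n_tc)) n_tc$values else n_tc
  if (is.null(spacing))
    spacing <- if (!is.null(n_tc$spacing)) n_tc$spacing else c(1, 1, 1)
  if (is.null(op)) op <- elastic_operator(materials, domain, spacing)
  # Forcing gradient of N with reflection ghosts: N itself satisfies a
  # no-flux condition at the breast boundary, so its normal gradient is 0
  # there (uniform N therefore forces nothing). u keeps Dirichlet ghosts.
  gradN <- function(axis) {
    if (dim(counts)[axis] == 1L) return(array(0, dim(counts)))
    np <- shift3(counts, axis, +1); mp <- shift3(op$mask, axis, +1, FALSE)
    nm <- shift3(counts, axis, -1); mm <- shift3(op$mask, axis, -1, FALSE)
    np[!mp] <- counts[!mp]
    nm[!mm] <- counts[!mm]
    (np - nm) / (2 * spacing[axis])
  }
  rhs <- do.call(c, lapply(1:3, function(l)
    materials$lambda * gradN(l)[op$mask]))
  sol <- as.numeric(Matrix::solve(op$chol, -rhs))
  u <- lapply(1:3, function(l) {
    a <- array(0, dim(op$mask))
    a[op$mask] <- sol[((l - 1) * op$n + 1):(l * op$n)]
    a
  })
  # strain tensor by central differences with the same zero ghosts
  grad <- function(a, axis) {
    (shift3(a, axis, +1) - shift3(a, axis, -1)) / (2 * spacing[axis])
  }
  e11 <- grad(u[[1]], 1); e22 <- grad(u[[2]], 2); e33 <- grad(u[[3]], 3)
  e12 <- (grad(u[[1]], 2) + grad(u[[2]], 1)) / 2
  e13 <- (grad(u[[1]], 3) + grad(u[[3]], 1)) / 2
  e23 <- (grad(u[[2]], 3) + grad(u[[3]], 2)) / 2
  G <- materials$G
  lam_l <- 2 * G * materials$nu / (1 - 2 * materials$nu)
  tr <- e11 + e22 + e33
  stress <- list(s11 = 2 * G * e11 + lam_l * tr,
                 s22 = 2 * G * e22 + lam_l * tr,
                 s33 = 2 * G * e33 + lam_l * tr,
                 s12 = 2 * G * e12, s13 = 2 * G * e13, s23 = 2 * G * e23)
  svm <- von_mises(stress)
  svm[!op$mask] <- 0
  structure(list(u = u, von_mises = svm, stress = stress),
            class = "mechanical_state")
}

#' Von Mises stress of a symmetric stress tensor field
#'
#' `sigma_vm = sqrt(0.5 * ((s11-s22)^2 + (s22-s33)^2 + (s33-s11)^2) +
#' 3 * (s12^2 + s13^2 + s23^2))`. Zero for hydrostatic stress, `|s|` for
#' uniaxial stress `s`, and `s * sqrt(3)` for pure shear `s`.
#'
#' @param stress named list with components `s11, s22, s33, s12, s13, s23`
#'   (arrays or scalars, kPa).
#' @return array (or scalar) of von Mises stress, kPa.
#' @export
von_mises <- function(stress) {
  with(stress, sqrt(pmax(
    0.5 * ((s11 - s22)^2 + (s22 - s33)^2 + (s33 - s11)^2) +
      3 * (s12^2 + s13^2 + s23^2), 0)))
}

#' Stress-damped tumor cell diffusivity
#'
#' `D = D0 * exp(-gamma * sigma_vm)`: the von Mises stress exponentially
#' damps the stress-free diffusion coefficient, so `D` lies in `(0, D0]`.
#'
#' @param d0 stress-free diffusion coefficient (mm^2/day), >= 0.
#' @param sigma_vm von Mises stress array or [image_volume()] (kPa).
#' @param gamma stress coupling constant (1/kPa), >= 0.
#' @return array (or `image_volume`, matching the input) of damped
#'   diffusivity.
#' @export
damp_diffusion <- function(d0, sigma_vm, gamma = 2.0e-3) {
  if (d0 < 0 || gamma < 0) stop("'d0' and 'gamma' must be nonnegative")
  if (is_image_volume(sigma_vm))
    return(volume_like(d0 * exp(-gamma * sigma_vm$values), sigma_vm))
  d0 * exp(-gamma * sigma_vm)
}
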