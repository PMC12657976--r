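# Linear-elastic tissue mechanics: equilibrium solve, von Mises stress, and
# stress-damped diffusivity.
#
# The displacement u solves div(sigma) = 0 on the breast mask with u = 0 on
# the mask boundary, where
#   sigma = lambda(x) div(u) I + mu(x) (grad u + grad u^T) - kappa N/theta I.
# Discretization is collocated central differences (one-sided at the mask
# boundary when assembling stresses). The operator depends only on E, nu and
# the mask, so its sparse Cholesky factor is computed once and cached; each
# stress refresh is a pair of triangular solves.

#' Mechanical parameter set for the breast domain
#'
#' Bundles the elastic constants and precomputes the Lame coefficient fields
#' `lambda = E nu / ((1 + nu)(1 - 2 nu))` and `mu = E / (2 (1 + nu))`. The
#' sparse elasticity operator and its factorization are built lazily on first
#' use and cached inside the object.
#'
#' @param E Young's modulus: a scalar (kPa) or a 3D field matching the mask.
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param kappa Tumor cell-force coupling constant, kPa.
#' @param gamma Stress-diffusion coupling constant, 1/kPa.
#' @param mask 3D logical breast mask.
#' @param voxel_size_mm Per-axis voxel spacing, mm.
#' @param stride Integer grid-coarsening factor for the equilibrium solve
#'   (default 1 = solve at full image resolution). With `stride > 1` the
#'   elasticity system is assembled on every `stride`-th voxel and the
#'   resulting stress interpolated back to the image grid; the stress field
#'   varies on the tumor scale, so a modest stride changes the damped
#'   diffusivity negligibly while cutting the factorization cost by orders
#'   of magnitude.
#' @return Object of class `mechanical_params` (environment).
#' @export
mechanical_params <- function(E, nu = 0.45, kappa = 1, gamma = 2e-2,
                              mask, voxel_size_mm = c(1, 1, 1.5),
                              stride = 1L) {
  if (!(nu > 0 && nu < 0.5)) stop("nu must lie in (0, 0.5)", call. = FALSE)
  if (length(E) == 1L) E <- array(E, dim = dim(mask))
  if (!identical(dim(E), dim(mask)))
    stop("E field must match the mask dimensions", call. = FALSE)
  if (any(E <= 0)) stop("E must be positive", call. = FALSE)
  stride <- max(1L, as.integer(stride))
  if (any(floor((dim(mask) - 1L) / stride) + 1L < 4L))
    stop("stride too large for the grid", call. = FALSE)
  p <- new.env(parent = emptyenv())
  p$E <- E; p$nu <- nu; p$kappa <- kappa; p$gamma <- gamma
  p$mask <- mask; p$h <- voxel_size_mm; p$stride <- stride
  p$lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  p$mu <- E / (2 * (1 + nu))
  class(p) <- "mechanical_params"
  p
}

# Strided-axis index sets for the coarse solve grid.
stride_axes <- function(d, stride)
  lapply(1:3, function(a) seq(1L, d[a], by = stride))

# Trilinear interpolation of a coarse-grid field back to the image grid.
# Coarse node j sits at fine index 1 + (j-1)*stride.
prolong_field <- function(fc, d_fine, stride) {
  if (stride == 1L) return(fc)
  out <- fc
  for (ax in 1:3) {
    dc <- dim(out)
    nf <- d_fine[ax]
    pos <- (seq_len(nf) - 1) / stride + 1    # fractional coarse coordinate
    j0 <- pmin(floor(pos), dc[ax] - 1L); j0 <- pmax(j0, 1L)
    w <- pmin(pmax(pos - j0, 0), 1)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(out, perm)
    dm <- dim(m)
    m2 <- matrix(m, nrow = dm[1])
    up <- m2[j0, , drop = FALSE] * (1 - w) + m2[j0 + 1L, , drop = FALSE] * w
    out <- aperm(array(up, c(nf, dm[2], dm[3])), order(perm))
  }
  out
}

# Sparse centered first-derivative operator along `axis` on the full grid.
centered_gradient_op <- function(d, h, axis) {
  n <- prod(d)
  lin <- array(seq_len(n), dim = d)
  sel_lo <- sel_hi <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  sel_lo[[axis]] <- seq_len(d[axis] - 1L)
  sel_hi[[axis]] <- seq_len(d[axis] - 1L) + 1L
  from <- as.vector(lin[sel_lo[[1]], sel_lo[[2]], sel_lo[[3]]])
  to <- as.vector(lin[sel_hi[[1]], sel_hi[[2]], sel_hi[[3]]])
  w <- 1 / (2 * h[axis])
  Matrix::sparseMatrix(i = c(from, to), j = c(to, from),
                       x = c(rep(w, length(from)), rep(-w, length(to))),
                       dims = c(n, n))
}

# Forward-difference face operator and face-averaged coefficient.
face_diff_op <- function(d, h, axis, coef) {
  n <- prod(d)
  lin <- array(seq_len(n), dim = d)
  sel_lo <- sel_hi <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  sel_lo[[axis]] <- seq_len(d[axis] - 1L)
  sel_hi[[axis]] <- seq_len(d[axis] - 1L) + 1L
  from <- as.vector(lin[sel_lo[[1]], sel_lo[[2]], sel_lo[[3]]])
  to <- as.vector(lin[sel_hi[[1]], sel_hi[[2]], sel_hi[[3]]])
  nf <- length(from)
  Dp <- Matrix::sparseMatrix(i = c(seq_len(nf), seq_len(nf)), j = c(from, to),
                             x = c(rep(-1 / h[axis], nf), rep(1 / h[axis], nf)),
                             dims = c(nf, n))
  cf <- 0.5 * (coef[from] + coef[to])
  list(Dp = Dp, cf = cf)
}

# Assemble (and cache) the restricted elasticity operator and its factor on
# the (possibly strided) solve grid.
mech_operator <- function(p) {
  if (!is.null(p$factor)) return(invisible(p))
  ax <- stride_axes(dim(p$mask), p$stride)
  mask_c <- p$mask[ax[[1]], ax[[2]], ax[[3]], drop = FALSE]
  lambda_c <- p$lambda[ax[[1]], ax[[2]], ax[[3]], drop = FALSE]
  mu_c <- p$mu[ax[[1]], ax[[2]], ax[[3]], drop = FALSE]
  d <- dim(mask_c); n <- prod(d); h <- p$h * p$stride
  # Unknowns: mask voxels whose full 6-neighborhood stays inside mask & grid
  # (Dirichlet u = 0 on the mask boundary layer).
  inner <- mask_c
  for (axis in 1:3) for (s in c(-1L, 1L)) {
    off <- integer(3); off[axis] <- s
    inner <- inner & shift_array(mask_c, off, fill = FALSE)
  }
  int <- which(inner)
  if (length(int) == 0L) stop("breast mask has no interior voxels", call. = FALSE)
  G <- lapply(1:3, function(a) centered_gradient_op(d, h, a))
  Lam <- Matrix::Diagonal(n, x = as.vector(lambda_c))
  Mu <- Matrix::Diagonal(n, x = as.vector(mu_c))
  B <- Reduce(`+`, lapply(1:3, function(a) {
    fd <- face_diff_op(d, h, a, mu_c)
    -Matrix::t(fd$Dp) %*% (Matrix::Diagonal(length(fd$cf), fd$cf) %*% fd$Dp)
  }))
  blocks <- vector("list", 9L)
  for (a in 1:3) for (b in 1:3) {
    K_ab <- G[[a]] %*% Lam %*% G[[b]] + G[[b]] %*% Mu %*% G[[a]]
    if (a == b) K_ab <- K_ab + B
    blocks[[(a - 1L) * 3L + b]] <- K_ab[int, int, drop = FALSE]
  }
  K <- rbind(cbind(blocks[[1]], blocks[[2]], blocks[[3]]),
             cbind(blocks[[4]], blocks[[5]], blocks[[6]]),
             cbind(blocks[[7]], blocks[[8]], blocks[[9]]))
  negK <- Matrix::forceSymmetric(-(K + Matrix::t(K)) / 2)
  p$factor <- tryCatch(Matrix::Cholesky(negK, LDL = FALSE, perm = TRUE),
                       error = function(e)
                         stop("elasticity operator is not positive definite: ",
                              conditionMessage(e), call. = FALSE))
  p$int <- int
  p$Gr <- lapply(G, function(g) g[int, , drop = FALSE])
  p$solve_grid <- list(axes = ax, mask = mask_c, lambda = lambda_c,
                       mu = mu_c, d = d, h = h)
  invisible(p)
}

# Mask-aware gradient: centered where both neighbors are in the mask,
# one-sided at the mask boundary, zero where no neighbor exists.
masked_gradient <- function(f, mask, h, axis) {
  off <- integer(3)
  off[axis] <- 1L
  f_up <- shift_array(f, -off, fill = 0); in_up <- shift_array(mask, -off, fill = FALSE)
  f_dn <- shift_array(f, off, fill = 0); in_dn <- shift_array(mask, off, fill = FALSE)
  g <- array(0, dim = dim(f))
  both <- in_up & in_dn
  g[both] <- (f_up[both] - f_dn[both]) / (2 * h[axis])
  up_only <- in_up & !in_dn
  g[up_only] <- (f_up[up_only] - f[up_only]) / h[axis]
  dn_only <- in_dn & !in_up
  g[dn_only] <- (f[dn_only] - f_dn[dn_only]) / h[axis]
  g[!mask] <- 0
  g
}

#' Solve mechanical equilibrium for the tumor-loaded breast
#'
#' Solves `div(sigma) = 0` for the displacement field generated by the tumor
#' expansion term `-kappa N/theta I`, assembles the Cauchy stress tensor and
#' the von Mises stress.
#'
#' @param params A [mechanical_params()] object.
#' @param cellularity 3D cell-number array, in `[0, theta]`.
#' @param theta Carrying capacity, cells/voxel.
#' @param fields `"all"` (default) or `"svm"`: with `"svm"` only the von
#'   Mises field is assembled and prolonged, which is what the forward model
#'   needs at every stress refresh.
#' @return Object of class `stress_state`: list with `u` (list of 3
#'   displacement arrays, mm), `sigma` (named list of the 6 tensor component
#'   arrays, kPa) and `svm` (von Mises stress array, kPa). With
#'   `fields = "svm"`, `u` and `sigma` are `NULL`.
#' @export
solve_equilibrium <- function(params, cellularity, theta,
                              fields = c("all", "svm")) {
  fields <- match.arg(fields)
  if (any(cellularity < -1e-9 | cellularity > theta * (1 + 1e-9), na.rm = TRUE))
    stop("cellularity must lie in [0, theta]", call. = FALSE)
  mech_operator(params)
  sg <- params$solve_grid
  d_fine <- dim(params$mask)
  cell_c <- cellularity[sg$axes[[1]], sg$axes[[2]], sg$axes[[3]], drop = FALSE]
  body <- as.vector(params$kappa * cell_c / theta)
  f <- unlist(lapply(params$Gr, function(g) as.vector(g %*% body)))
  # K u = f with negK factorized: u = -(negK)^{-1} f
  u_int <- -as.vector(Matrix::solve(params$factor, f, system = "A"))
  ni <- length(params$int)
  u <- lapply(1:3, function(a) {
    ua <- array(0, dim = sg$d)
    ua[params$int] <- u_int[(a - 1L) * ni + seq_len(ni)]
    ua
  })
  g <- function(comp, ax) masked_gradient(u[[comp]], sg$mask, sg$h, ax)
  uxx <- g(1, 1); uyy <- g(2, 2); uzz <- g(3, 3)
  uxy <- g(1, 2); uyx <- g(2, 1)
  uxz <- g(1, 3); uzx <- g(3, 1)
  uyz <- g(2, 3); uzy <- g(3, 2)
  divu <- uxx + uyy + uzz
  lam <- sg$lambda; mu <- sg$mu
  press <- params$kappa * cell_c / theta
  sigma <- list(
    xx = lam * divu + 2 * mu * uxx - press,
    yy = lam * divu + 2 * mu * uyy - press,
    zz = lam * divu + 2 * mu * uzz - press,
    xy = mu * (uxy + uyx),
    xz = mu * (uxz + uzx),
    yz = mu * (uyz + uzy))
  if (fields == "svm") {
    svm <- von_mises(sigma$xx, sigma$yy, sigma$zz, sigma$xy, sigma$xz,
                     sigma$yz)
    if (params$stride > 1L)
      svm <- prolong_field(svm, d_fine = d_fine, stride = params$stride)
    return(structure(list(u = NULL, sigma = NULL, svm = svm),
                     class = "stress_state"))
  }
  if (params$stride > 1L) {
    u <- lapply(u, prolong_field, d_fine = d_fine, stride = params$stride)
    sigma <- lapply(sigma, prolong_field, d_fine = d_fine,
                    stride = params$stride)
  }
  svm <- von_mises(sigma$xx, sigma$yy, sigma$zz, sigma$xy, sigma$xz, sigma$yz)
  structure(list(u = u, sigma = sigma, svm = svm), class = "stress_state")
}

#' Von Mises stress from Cauchy tensor components
#'
#' `sqrt(0.5 * ((sxx-syy)^2 + (sxx-szz)^2 + (szz-syy)^2 + 6 (sxy^2 + sxz^2 +
#' syz^2)))`. The `6 * (...)` inside the half equals `3 * (...)` outside.
#'
#' @param sxx,syy,szz,sxy,sxz,syz Stress component arrays (kPa).
#' @return Array of von Mises stress, kPa (non-negative).
#' @export
von_mises <- function(sxx, syy, szz, sxy = 0, sxz = 0, syz = 0) {
  sqrt(0.5 * ((sxx - syy)^2 + (sxx - szz)^2 + (szz - syy)^2 +
                6 * (sxy^2 + sxz^2 + syz^2)))
}

#' Stress-damped diffusivity field
#'
#' `D = D0 exp(-gamma sigma_vm)`: cell mobility decays exponentially with
#' local von Mises stress.
#'
#' @param D0 Free diffusivity, mm^2/day.
#' @param gamma Coupling constant, 1/kPa.
#' @param svm Von Mises stress array, kPa.
#' @return Diffusivity array, mm^2/day; in `(0, D0]` for non-negative stress.
#' @export
damped_diffusivity <- function(D0, gamma, svm) {
  if (D0 < 0 || gamma < 0) stop("D0 and gamma must be non-negative", call. = FALSE)
  D0 * exp(-gamma * svm)
}
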