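# Quasi-static conduction solve and tetrapolar transfer impedance.
#
# The conduction equation div(sigma grad phi) = 0 is discretized by a
# 7-point finite-volume stencil with harmonic-mean face conductivities. All
# outer boundaries are insulating except the current-electrode footprints,
# where the total current +/- I is distributed uniformly over the footprint
# faces. The potential gauge is zero mean over the conduction domain. The
# system is solved matrix-free with Jacobi-preconditioned conjugate
# gradients (relative residual 1e-8, iteration cap 1e5 by default).

#' Stimulation pattern for a tetrapolar measurement
#'
#' Pairs the current-carrying footprints (C1 source, C2 sink) with the
#' voltage pick-up footprints (M1, M2). Footprints are vectors of linear
#' voxel indices, typically from [place_electrode_array()].
#'
#' @param footprints Named list with elements `C1`, `M1`, `M2`, `C2`, e.g.
#'   the `footprints` element of a built model.
#' @param current_mA Injected current amplitude (mA), default 3.
#' @return An object of class `stimulation_pattern`.
#' @export
stimulation_pattern <- function(footprints, current_mA = 3) {
  need <- c("C1", "M1", "M2", "C2")
  if (!all(need %in% names(footprints)))
    stop("footprints must contain C1, M1, M2, C2")
  fp <- lapply(footprints[need], as.integer)
  if (any(lengths(fp) == 0)) stop("empty electrode footprint")
  if (anyDuplicated(unlist(fp)))
    stop("electrode footprints must be pairwise disjoint")
  chk_pos(current_mA, "current_mA")
  structure(list(C1 = fp$C1, M1 = fp$M1, M2 = fp$M2, C2 = fp$C2,
                 current_mA = current_mA),
            class = "stimulation_pattern")
}

#' Assemble the conduction system
#'
#' Builds the right-hand side (injected current, in amperes, distributed
#' uniformly over the current-electrode footprint faces; it sums to zero by
#' charge conservation) and bundles it with the conductivity field and
#' stimulation pattern. The operator itself is applied matrix-free by the
#' solver; [conduction_matrix()] materializes it as a sparse matrix for
#' inspection on small grids.
#'
#' @param field A [to_conductivity_field()] result.
#' @param pattern A [stimulation_pattern()].
#' @return An object of class `conduction_system`.
#' @export
assemble_conduction_system <- function(field, pattern) {
  stopifnot(inherits(field, "conductivity_field"),
            inherits(pattern, "stimulation_pattern"))
  sig <- field$sigma
  idx <- c(pattern$C1, pattern$M1, pattern$M2, pattern$C2)
  if (any(idx < 1 | idx > length(sig)))
    stop("electrode footprint outside the grid")
  if (any(sig[idx] <= 0))
    stop("electrode footprint touches non-conducting voxels")
  I <- pattern$current_mA / 1000  # A
  b <- numeric(length(sig))
  b[pattern$C1] <- I / length(pattern$C1)
  b[pattern$C2] <- -I / length(pattern$C2)
  structure(list(field = field, pattern = pattern, b = b),
            class = "conduction_system")
}

#' Sparse matrix of the assembled conduction operator
#'
#' Materializes the finite-volume operator as a symmetric sparse matrix over
#' the conducting voxels, for inspection and for direct-solve cross-checks
#' on small grids (the production path never forms it).
#'
#' @param system A [assemble_conduction_system()] result.
#' @return A list: `A` (dgCMatrix, Siemens), `b` (A, over conducting voxels),
#'   `index` mapping matrix rows to linear voxel indices.
#' @export
conduction_matrix <- function(system) {
  stopifnot(inherits(system, "conduction_system"))
  field <- system$field
  sig <- field$sigma
  dims <- field$dims
  act <- which(sig > 0)
  if (length(act) > 5e5)
    stop("conduction_matrix is meant for small grids (< 5e5 active voxels)")
  row_of <- integer(length(sig))
  row_of[act] <- seq_along(act)
  h_m <- field$h / 1000
  harm <- function(a, b) 2 * a * b / (a + b)

  ii <- list(); jj <- list(); xx <- list(); k <- 0
  ar <- arrayInd(act, dims)
  for (axis in 1:3) {
    step <- c(1, dims[1], dims[1] * dims[2])[axis]
    ok <- ar[, axis] < dims[axis]
    nb <- act[ok] + step
    ok2 <- sig[nb] > 0
    i <- act[ok][ok2]; j <- nb[ok2]
    if (!length(i)) next
    g <- h_m * harm(sig[i], sig[j])
    k <- k + 1
    ii[[k]] <- c(row_of[i], row_of[j]); jj[[k]] <- c(row_of[j], row_of[i])
    xx[[k]] <- c(-g, -g)
  }
  ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)
  off <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = rep(length(act), 2))
  d <- -Matrix::rowSums(off)
  A <- off + Matrix::Diagonal(length(act), d)
  list(A = A, b = system$b[act], index = act)
}

#' Solve the conduction problem for the electric potential
#'
#' Matrix-free Jacobi-preconditioned conjugate-gradient solve of the
#' assembled system, deterministic for fixed input. The potential is
#' reported at voxel centres with zero mean over the conduction domain
#' (`NA` outside it).
#'
#' @param system A [assemble_conduction_system()] result.
#' @param tol Relative residual tolerance, default 1e-8.
#' @param maxit Iteration cap, default 1e5.
#' @return An object of class `potential_field`: `phi` (V, 3-D array),
#'   `iterations`, `relres`, and the originating system.
#' @export
solve_potential <- function(system, tol = 1e-8, maxit = 1e5) {
  stopifnot(inherits(system, "conduction_system"))
  field <- system$field
  b <- system$b
  b_act <- b[field$sigma > 0]
  # enforce exact consistency (sum b = 0) against rounding in the split
  if (abs(sum(b_act)) > 0) b[field$sigma > 0] <- b_act - sum(b_act) / length(b_act)
  res <- .pcg_solve(as.numeric(field$sigma), b, as.integer(field$dims),
                    field$h / 1000, tol, as.integer(maxit))
  if (!res$converged)
    stop("conjugate gradients did not reach tolerance ", tol, " in ",
         res$iterations, " iterations (relative residual ",
         signif(res$relres, 3), "); the conduction domain may be disconnected")
  structure(list(phi = array(res$phi, dim = field$dims),
                 iterations = res$iterations, relres = res$relres,
                 gauge = "zero mean over conduction domain",
                 field = field, pattern = system$pattern),
            class = "potential_field")
}

#' Tetrapolar transfer impedance from a solved potential
#'
#' `Z = (mean phi over M1 - mean phi over M2) / I`. With the standard
#' in-line order C1-M1-M2-C2 (M1 nearer the current source C1) the sign is
#' positive.
#'
#' @param phi A [solve_potential()] result.
#' @param pattern The [stimulation_pattern()] the potential was solved for
#'   (defaults to the one stored in `phi`).
#' @return Transfer impedance (Ohm).
#' @export
transfer_impedance <- function(phi, pattern = phi$pattern) {
  stopifnot(inherits(phi, "potential_field"),
            inherits(pattern, "stimulation_pattern"))
  p <- phi$phi
  v1 <- p[pattern$M1]; v2 <- p[pattern$M2]
  if (any(is.na(c(v1, v2))))
    stop("measurement footprint lies outside the conduction domain")
  (mean(v1) - mean(v2)) / (pattern$current_mA / 1000)
}

#' One-call forward solve
#'
#' Convenience wrapper: assemble, solve, and return the transfer impedance.
#'
#' @inheritParams assemble_conduction_system
#' @inheritParams solve_potential
#' @param details If `TRUE`, also return the potential field.
#' @return Impedance (Ohm), or a list with `Z`, `phi`, `iterations` when
#'   `details = TRUE`.
#' @export
solve_tetrapolar <- function(field, pattern, tol = 1e-8, maxit = 1e5,
                             details = FALSE) {
  phi <- solve_potential(assemble_conduction_system(field, pattern),
                         tol = tol, maxit = maxit)
  Z <- transfer_impedance(phi, pattern)
  if (details) list(Z = Z, phi = phi, iterations = phi$iterations) else Z
}

#' Analytic tetrapolar impedance on a homogeneous half-space
#'
#' For point electrodes on a homogeneous half-space of resistivity `rho`,
#' with current electrodes at +/- `a` and measuring electrodes at +/- `b`
#' from the array centre (a symmetric in-line array), the transfer impedance
#' is `Z = 2 rho b / (pi (a^2 - b^2))`. For an equidistant array with
#' adjacent spacing d (`a = 1.5 d`, `b = 0.5 d`) this reduces to the Wenner
#' value `rho / (2 pi d)`.
#'
#' @param rho Resistivity (Ohm*m).
#' @param a Half the current-electrode separation (m).
#' @param b Half the measuring-electrode separation (m); `0 <= b < a`.
#' @return Impedance (Ohm).
#' @export
analytic_tetrapolar <- function(rho, a, b) {
  if (any(rho <= 0)) stop("rho must be positive")
  if (any(b < 0) || any(a <= b))
    stop("need a > b >= 0 (half current / measuring separations)")
  2 * rho * b / (pi * (a^2 - b^2))
}

#' Analytic tetrapolar impedance in a finite insulating box
#'
#' Exact continuum transfer impedance for electrodes on the surface of a
#' homogeneous rectangular block with insulating walls, computed by the
#' method of images (a lattice of mirror sources across the six faces).
#' For a block much larger than the array this converges to the half-space
#' value of [analytic_tetrapolar()]; on a finite block it additionally
#' captures the wall effect, which makes it the reference of choice for
#' grid-convergence studies of the finite-volume solver.
#'
#' The block occupies `[-width/2, width/2] x [0, depth] x
#' [-length/2, length/2]` (the skin face is y = 0, matching
#' [block_grid()]). Each electrode is a set of surface points `(x, z)`;
#' current is injected uniformly over the set and potentials are averaged
#' over it, matching the solver's electrode model.
#'
#' @param rho Resistivity (Ohm*m).
#' @param width,depth,length Block dimensions (m).
#' @param C1,M1,M2,C2 Two-column matrices of surface point coordinates
#'   `(x, z)` in metres, or length-2 vectors for single points.
#' @param K Image-lattice truncation order (images per axis direction);
#'   the tetrapolar difference converges rapidly, the default is ample for
#'   arrays well inside the block.
#' @return Transfer impedance (Ohm).
#' @export
analytic_tetrapolar_box <- function(rho, width, depth, length, C1, M1, M2, C2,
                                    K = 8) {
  chk_pos(c(rho, width, depth, length), "rho and box dimensions")
  as_pts <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = FALSE)
    stopifnot(ncol(p) == 2)
    p
  }
  ks <- -K:K
  # image coordinates per axis for a source coordinate c between two
  # insulating planes; a surface source (y = 0) double-counts onto itself,
  # which reproduces the half-space factor
  x_img <- function(c) c(c + 2 * ks * width, -width - c + 2 * ks * width)
  y_img <- c(2 * ks * depth, 2 * ks * depth)
  z_img <- function(c) c(c + 2 * ks * length, -length - c + 2 * ks * length)
  y2 <- y_img^2
  G <- function(P, Q) {
    P <- as_pts(P); Q <- as_pts(Q)
    tot <- 0
    for (i in seq_len(nrow(P))) {
      xi <- x_img(P[i, 1]); zi <- z_img(P[i, 2])
      for (j in seq_len(nrow(Q))) {
        r2xy <- outer((xi - Q[j, 1])^2, y2, "+")
        tot <- tot + sum(1 / sqrt(outer(as.numeric(r2xy),
                                        (zi - Q[j, 2])^2, "+")))
      }
    }
    tot / (nrow(P) * nrow(Q)) * rho / (4 * pi)
  }
  G(C1, M1) - G(C2, M1) - G(C1, M2) + G(C2, M2)
}

#' Reciprocity check of the forward solve
#'
#' Swaps the roles of the current and measuring pairs and reports the
#' relative impedance difference. By the reciprocity theorem the continuum
#' transfer impedance is invariant under the swap; the discrete residual is
#' bounded by the solver tolerance and provides a solver/model validity
#' check.
#'
#' @param field A `conductivity_field`.
#' @param pattern A [stimulation_pattern()].
#' @param tol Solver tolerance passed to [solve_potential()].
#' @return List: `error` (relative difference), `Z_direct`, `Z_swapped`.
#' @export
reciprocity_error <- function(field, pattern, tol = 1e-8) {
  swapped <- stimulation_pattern(list(C1 = pattern$M1, M1 = pattern$C1,
                                      M2 = pattern$C2, C2 = pattern$M2),
                                 current_mA = pattern$current_mA)
  Z1 <- solve_tetrapolar(field, pattern, tol = tol)
  Z2 <- solve_tetrapolar(field, swapped, tol = tol)
  list(error = abs(Z1 - Z2) / abs(Z1), Z_direct = Z1, Z_swapped = Z2)
}
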