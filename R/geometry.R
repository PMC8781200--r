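# Voxelization of the perirenal model.
#
# Coordinate convention (right-handed): x medio-lateral, y postero-anterior
# with the posterior skin tangent plane at y = 0 (the body interior is
# y > 0), z cranio-caudal. Voxel centres are sampled; labels() codes follow
# tissue_levels() with 0 = outside.

label_code <- function(name) match(name, tissue_levels()) - 1L

# minimum distance from interior cross-section points to the trunk-ellipse
# boundary, by dense boundary sampling (chunked to bound memory)
dist_to_ellipse <- function(px, py, a, b, cy, nb = 1440L) {
  t <- seq(0, 2 * pi, length.out = nb + 1L)[-(nb + 1L)]
  bx <- a * cos(t)
  by <- cy + b * sin(t)
  n <- length(px)
  out <- numeric(n)
  chunk <- 4000L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(px[s:e], bx, "-")^2
    d2 <- d2 + outer(py[s:e], by, "-")^2
    out[s:e] <- sqrt(.rowMins(d2))
  }
  out
}

.rowMins <- function(m) {
  # pmin over columns without building an apply() overhead per row
  out <- m[, 1L]
  for (j in 2L:ncol(m)) out <- pmin(out, m[, j])
  out
}

# integer label matrix for one trunk cross-section (x fast, y slow)
cross_section_labels <- function(torso, xs, ys) {
  a <- torso$major_axis / 2
  b <- torso$minor_axis / 2
  nx <- length(xs); ny <- length(ys)
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  inside <- (X / a)^2 + ((Y - b) / b)^2 <= 1
  lab <- matrix(label_code("outside"), nx, ny)
  idx <- which(inside)
  d <- dist_to_ellipse(X[idx], Y[idx], a, b, cy = b)
  code <- ifelse(d <= torso$h_subc, label_code("subcutaneous_fat"),
          ifelse(d <= torso$h_subc + torso$h_m, label_code("muscle"),
                 label_code(torso$background_tissue)))
  lab[idx] <- code
  lab
}

#' Build the voxelized patient model
#'
#' Constructs the tissue label grid for the layered trunk / two-layer kidney
#' model and records the electrode-array footprints on the posterior skin
#' surface. Moving inward from the skin along the electrode normal the layers
#' are subcutaneous fat, muscle, then abdominal background; the kidney
#' (cortex shell around a medulla core) sits at its specified depth inside a
#' perirenal fat capsule.
#'
#' @param torso A [torso_spec()].
#' @param kidney A [kidney_spec()].
#' @param array An [electrode_array_spec()]; its footprints are placed on the
#'   skin and stored in the returned grid.
#' @param h Voxel edge length (mm). Must not exceed the cortex thickness
#'   `h_c`, otherwise the cortex shell would be unresolvable.
#' @return An object of class `label_grid`: a list with `h` (mm), `dims`,
#'   `origin` (mm, centre of voxel `[1,1,1]`), integer array `labels`
#'   (codes into [tissue_levels()], 0 = outside), surface map `surf_iy`,
#'   electrode `footprints`, and the input specs.
#' @export
build_patient_model <- function(torso, kidney, array, h = 2) {
  stopifnot(inherits(torso, "torso_spec"), inherits(kidney, "kidney_spec"),
            inherits(array, "electrode_array_spec"))
  if (h > kidney$h_c)
    stop_geometry("voxel size h = ", h, " mm exceeds the cortex thickness ",
                  kidney$h_c, " mm; the cortex shell would be unresolvable")
  validate_kidney_in_torso(kidney, torso)

  a <- torso$major_axis / 2
  b <- torso$minor_axis / 2
  nx <- as.integer(ceiling(torso$major_axis / h))
  ny <- as.integer(ceiling(torso$minor_axis / h)) + 1L
  nz <- as.integer(ceiling(torso$axial_length / h))
  # x and z centred on the torso axis (mirror-symmetric grids); y starts at
  # the posterior tangent plane
  xs <- (seq_len(nx) - (nx + 1) / 2) * h
  ys <- (seq_len(ny) - 0.5) * h
  zs <- (seq_len(nz) - (nz + 1) / 2) * h
  origin <- c(xs[1], ys[1], zs[1])

  lab2d <- cross_section_labels(torso, xs, ys)
  labels <- array(as.integer(lab2d), dim = c(nx, ny, nz))

  # kidney + capsule, restricted to the bounding box
  x0 <- kidney$lateral_offset
  y0 <- skin_height(torso, x0) + kidney$depth + kidney$semi_axes[3]
  z0 <- 0
  sz <- kidney$semi_axes[1]; sx <- kidney$semi_axes[2]; sy <- kidney$semi_axes[3]
  m  <- kidney$capsule_margin
  ix <- which(abs(xs - x0) <= sx + m + h)
  iy <- which(abs(ys - y0) <= sy + m + h)
  iz <- which(abs(zs - z0) <= sz + m + h)
  if (!length(ix) || !length(iy) || !length(iz))
    stop_geometry("kidney lies outside the voxel grid")
  gx <- (xs[ix] - x0); gy <- (ys[iy] - y0); gz <- (zs[iz] - z0)
  EX <- array(gx, dim = c(length(ix), length(iy), length(iz)))
  EY <- aperm(array(gy, dim = c(length(iy), length(ix), length(iz))), c(2, 1, 3))
  EZ <- aperm(array(gz, dim = c(length(iz), length(ix), length(iy))), c(2, 3, 1))
  e_caps <- (EX / (sx + m))^2 + (EY / (sy + m))^2 + (EZ / (sz + m))^2
  e_kid  <- (EX / sx)^2 + (EY / sy)^2 + (EZ / sz)^2
  hc <- kidney$h_c
  e_med  <- (EX / (sx - hc))^2 + (EY / (sy - hc))^2 + (EZ / (sz - hc))^2

  sub <- labels[ix, iy, iz, drop = FALSE]
  bg <- label_code("background")
  kid_mask <- e_kid <= 1
  if (any(kid_mask & sub != bg))
    stop_geometry("kidney ellipsoid intersects the body-wall layers or the ",
                  "grid boundary; increase depth or shrink the kidney")
  # capsule only claims background voxels: perirenal fat may abut (and is
  # clipped by) the muscle wall
  sub[e_caps <= 1 & sub == bg] <- label_code("perirenal_fat")
  sub[kid_mask] <- label_code("cortex")
  sub[e_med <= 1] <- label_code("medulla")
  labels[ix, iy, iz] <- sub

  # skin surface map: first in-body voxel along +y per medio-lateral column
  # (constant along z for an extruded trunk)
  outside <- label_code("outside")
  surf_iy <- apply(labels[, , 1L, drop = TRUE] != outside, 1L,
                   function(col) if (any(col)) which(col)[1L] else NA_integer_)

  grid <- structure(list(h = h, dims = c(nx, ny, nz), origin = origin,
                         labels = labels, surf_iy = as.integer(surf_iy),
                         torso = torso, kidney = kidney, array = array,
                         footprints = NULL),
                    class = "label_grid")
  grid$footprints <- place_electrode_array(grid, array)
  grid
}

# physical voxel-centre coordinates along each axis
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$dims[1]) - 1) * grid$h,
       y = grid$origin[2] + (seq_len(grid$dims[2]) - 1) * grid$h,
       z = grid$origin[3] + (seq_len(grid$dims[3]) - 1) * grid$h)
}

#' Place the tetrapolar array on the skin surface
#'
#' Rasterizes the four electrode disks onto the skin face of the voxel grid.
#' Electrode centres are collinear along the body axis at the array centre's
#' medio-lateral position, in line order C1, M1, M2, C2 at body-axis offsets
#' -1.5d, -0.5d, +0.5d, +1.5d, so the measuring pair is separated by the
#' adjacent spacing d and the current pair by 3d. Each footprint is the set
#' of skin-surface voxels whose column centre falls within the disk radius
#' (at least the nearest column).
#'
#' @param grid A `label_grid` from [build_patient_model()] (or [block_grid()]).
#' @param array An [electrode_array_spec()].
#' @return Named list (`C1`, `M1`, `M2`, `C2`) of linear voxel indices into
#'   the label array, with the nominal electrode centres as attribute
#'   `centers`.
#' @export
place_electrode_array <- function(grid, array) {
  stopifnot(inherits(grid, "label_grid"),
            inherits(array, "electrode_array_spec"))
  ax <- grid_axes(grid)
  ctr <- array$center
  if (is.null(ctr)) {
    x_c <- if (!is.null(grid$kidney)) grid$kidney$lateral_offset else 0
    ctr <- c(x_c, 0)
  }
  d <- array$spacing
  r <- array$disk_diameter / 2
  zc <- ctr[2] + c(-1.5, -0.5, 0.5, 1.5) * d
  names(zc) <- c("C1", "M1", "M2", "C2")
  if (min(zc) < ax$z[1] - grid$h / 2 || max(zc) > ax$z[length(ax$z)] + grid$h / 2)
    stop_geometry("electrode array (current-pair span ", 3 * d, " mm) falls ",
                  "off the grid along the body axis")

  nx <- grid$dims[1]; ny <- grid$dims[2]
  foot <- lapply(seq_along(zc), function(k) {
    DX <- outer(ax$x - ctr[1], rep(1, length(ax$z)))
    DZ <- outer(rep(1, length(ax$x)), ax$z - zc[k])
    sel <- which(DX^2 + DZ^2 <= r^2, arr.ind = TRUE)
    if (nrow(sel) == 0) {
      ixn <- which.min(abs(ax$x - ctr[1]))
      izn <- which.min(abs(ax$z - zc[k]))
      sel <- cbind(ixn, izn)
    }
    iy <- grid$surf_iy[sel[, 1]]
    if (any(is.na(iy)))
      stop_geometry("electrode footprint lies off the skin surface")
    as.integer(sel[, 1] + nx * (iy - 1L) + nx * ny * (sel[, 2] - 1L))
  })
  names(foot) <- names(zc)
  if (anyDuplicated(unlist(foot)))
    stop_geometry("electrode footprints overlap on the voxel grid; increase ",
                  "spacing or refine the grid")
  attr(foot, "centers") <- zc
  attr(foot, "center_x") <- ctr[1]
  foot
}

#' Surface coordinates of electrode footprints
#'
#' Returns the physical `(x, z)` coordinates (mm) of the skin-surface voxel
#' columns making up each electrode footprint — the realized (rasterized)
#' electrode geometry, e.g. for evaluating an analytic reference at the
#' positions the solver actually uses.
#'
#' @param grid A `label_grid`.
#' @param footprints Footprint list from [place_electrode_array()];
#'   defaults to the one stored in the grid.
#' @return Named list of two-column matrices (x_mm, z_mm).
#' @export
footprint_coords <- function(grid, footprints = grid$footprints) {
  stopifnot(inherits(grid, "label_grid"), !is.null(footprints))
  ax <- grid_axes(grid)
  lapply(footprints, function(idx) {
    ai <- arrayInd(idx, grid$dims)
    cbind(x_mm = ax$x[ai[, 1]], z_mm = ax$z[ai[, 3]])
  })
}

#' Homogeneous rectangular block grid
#'
#' A uniform block of a single tissue with a flat skin face at y = 0, used
#' for half-space validation of the solver against the analytic tetrapolar
#' formula (the block emulates a half-space when its lateral extent is large
#' compared with the current-electrode separation).
#'
#' @param width Medio-lateral extent (mm).
#' @param depth Postero-anterior extent (mm).
#' @param length Body-axis extent (mm).
#' @param h Voxel edge (mm).
#' @param tissue Tissue label for the block interior.
#' @return A `label_grid` (without torso/kidney specs).
#' @export
block_grid <- function(width, depth, length, h, tissue = "background") {
  chk_pos(c(width, depth, length, h), "block dimensions")
  nx <- as.integer(ceiling(width / h))
  ny <- as.integer(ceiling(depth / h))
  nz <- as.integer(ceiling(length / h))
  labels <- array(label_code(tissue), dim = c(nx, ny, nz))
  structure(list(h = h, dims = c(nx, ny, nz),
                 origin = c(-(nx - 1) / 2 * h, h / 2, -(nz - 1) / 2 * h),
                 labels = labels, surf_iy = rep(1L, nx),
                 torso = NULL, kidney = NULL, array = NULL,
                 footprints = NULL),
            class = "label_grid")
}

#' Per-tissue volumes of a label grid
#'
#' @param grid A `label_grid`.
#' @return Named numeric vector of tissue volumes in mm^3 (voxel count times
#'   voxel volume), including `outside`.
#' @export
tissue_volumes <- function(grid) {
  stopifnot(inherits(grid, "label_grid"))
  lv <- tissue_levels()
  counts <- tabulate(grid$labels + 1L, nbins = length(lv))
  stats::setNames(counts * grid$h^3, lv)
}

#' @export
print.label_grid <- function(x, ...) {
  cat(sprintf("Voxel label grid: %d x %d x %d at h = %g mm (%d voxels)\n",
              x$dims[1], x$dims[2], x$dims[3], x$h, prod(x$dims)))
  v <- tissue_volumes(x) / 1000
  v <- v[v > 0]
  cat("  tissue volumes (cm^3):",
      paste(sprintf("%s %.1f", names(v), v), collapse = ", "), "\n")
  invisible(x)
}
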