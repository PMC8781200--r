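#' @useDynLib renalimp, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Tissue labels used in the voxel model
#'
#' Integer-coded tissue labels of the perirenal voxel model, in fixed order.
#' Code 0 (`outside`) marks voxels outside the conduction domain.
#'
#' @return Character vector of the seven label names.
#' @export
tissue_levels <- function() {
  c("outside", "subcutaneous_fat", "muscle", "perirenal_fat",
    "cortex", "medulla", "background")
}

stop_geometry <- function(...) {
  stop(structure(class = c("renalimp_geometry_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

chk_pos <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop_geometry(what, " must be a positive finite number")
}

#' Trunk (torso) geometry specification
#'
#' The trunk cross-section is an ellipse with major axis `major_axis`
#' (medio-lateral) and minor axis `minor_axis` (postero-anterior), extruded
#' along the body axis over `axial_length`. Moving inward from the skin, the
#' body wall is a subcutaneous-fat layer of thickness `h_subc` followed by a
#' muscle layer of thickness `h_m`; the remaining interior is filled with
#' `background_tissue` (abdominal contents). All lengths in millimetres.
#' Defaults are the reference adult model measured from MRI.
#'
#' @param major_axis Full major axis 2a1 of the trunk ellipse (mm).
#' @param minor_axis Full minor axis 2b1 of the trunk ellipse (mm).
#' @param h_subc Subcutaneous fat thickness (mm).
#' @param h_m Muscle layer thickness (mm).
#' @param axial_length Modelled trunk segment length along the body axis (mm).
#'   The default keeps the grid boundary several current-electrode spacings
#'   away from the array, which controls domain-truncation error.
#' @param background_tissue Label filling the interior not otherwise assigned.
#' @return An object of class `torso_spec`.
#' @export
torso_spec <- function(major_axis = 253.7, minor_axis = 166.71,
                       h_subc = 5.54, h_m = 10.74, axial_length = 400,
                       background_tissue = "background") {
  chk_pos(major_axis, "major_axis"); chk_pos(minor_axis, "minor_axis")
  chk_pos(h_subc, "h_subc"); chk_pos(h_m, "h_m")
  chk_pos(axial_length, "axial_length")
  if (h_subc + h_m >= minor_axis / 2)
    stop_geometry("body-wall layers (h_subc + h_m) must be thinner than the ",
                  "torso minor semi-axis")
  if (!background_tissue %in% tissue_levels())
    stop_geometry("unknown background tissue '", background_tissue, "'")
  structure(list(major_axis = major_axis, minor_axis = minor_axis,
                 h_subc = h_subc, h_m = h_m, axial_length = axial_length,
                 background_tissue = background_tissue),
            class = "torso_spec")
}

#' Kidney geometry specification
#'
#' The kidney is a two-layer ellipsoid: a cortex shell of uniform thickness
#' `h_c` around a medulla core, wrapped in a perirenal-fat capsule of
#' thickness `capsule_margin`. `semi_axes` gives the three semi-axes in the
#' order (cranio-caudal, medio-lateral, postero-anterior); the long axis lies
#' along the body axis. `depth` is measured from the posterior skin surface
#' (above the kidney centre) to the nearest kidney surface along the
#' postero-anterior direction; `lateral_offset` shifts the kidney centre off
#' the mid-sagittal plane. All lengths in millimetres.
#'
#' The reference values for `semi_axes`, `depth`, `lateral_offset` and
#' `capsule_margin` are typical adult anatomy (the source MRI dimensions are
#' not published); they are plain config values and can be overridden. The
#' default kidney is low-normal adult size (90 x 50 x 30 mm): together with
#' the 5 mm cortex shell this keeps the cortex the majority of kidney volume,
#' as it is anatomically — a medulla-dominant two-layer kidney would invert
#' the sensitivity ordering of the perfusion cases.
#'
#' @param semi_axes Three kidney semi-axes (mm), cranio-caudal first.
#' @param h_c Cortex shell thickness (mm); must satisfy `0 < h_c < min(semi_axes)`.
#' @param depth Skin-to-kidney distance (mm).
#' @param lateral_offset Medio-lateral shift of the kidney centre (mm).
#' @param capsule_margin Perirenal fat thickness around the kidney (mm).
#' @return An object of class `kidney_spec`.
#' @export
kidney_spec <- function(semi_axes = c(45, 25, 15), h_c = 5, depth = 26.28,
                        lateral_offset = 60, capsule_margin = 10) {
  if (length(semi_axes) != 3) stop_geometry("semi_axes must have length 3")
  chk_pos(semi_axes, "semi_axes"); chk_pos(h_c, "h_c"); chk_pos(depth, "depth")
  chk_pos(capsule_margin, "capsule_margin")
  if (!is.numeric(lateral_offset) || !is.finite(lateral_offset))
    stop_geometry("lateral_offset must be finite")
  if (h_c >= min(semi_axes))
    stop_geometry("cortex thickness h_c must be smaller than the smallest ",
                  "kidney semi-axis")
  structure(list(semi_axes = as.numeric(semi_axes), h_c = h_c, depth = depth,
                 lateral_offset = lateral_offset,
                 capsule_margin = capsule_margin),
            class = "kidney_spec")
}

#' In-line four-electrode array specification
#'
#' Four disk electrodes in line along the body axis (the kidney longitudinal
#' axis), equidistant with adjacent spacing `spacing`: current electrodes C1
#' and C2 outermost (separation `3 * spacing`), measuring electrodes M1 and
#' M2 innermost (separation `spacing`). Disks have diameter `disk_diameter`
#' and sit on the posterior skin surface.
#'
#' @param spacing Adjacent electrode spacing d (mm); must exceed
#'   `disk_diameter` so footprints cannot overlap.
#' @param disk_diameter Electrode base diameter (mm), default 3.
#' @param center Surface coordinate `c(x, z)` (mm) of the array centre:
#'   medio-lateral position and body-axis position. `NULL` centres the array
#'   over the kidney projection when the model is built.
#' @param current_mA Injected current amplitude (mA), default 3.
#' @return An object of class `electrode_array_spec`.
#' @export
electrode_array_spec <- function(spacing = 20, disk_diameter = 3,
                                 center = NULL, current_mA = 3) {
  chk_pos(spacing, "spacing"); chk_pos(disk_diameter, "disk_diameter")
  chk_pos(current_mA, "current_mA")
  if (spacing <= disk_diameter)
    stop_geometry("electrode spacing (", spacing, " mm) must exceed the disk ",
                  "diameter (", disk_diameter, " mm): footprints overlap")
  if (!is.null(center)) {
    if (length(center) != 2 || any(!is.finite(center)))
      stop_geometry("center must be c(x, z) in mm")
    center <- as.numeric(center)
  }
  structure(list(spacing = spacing, disk_diameter = disk_diameter,
                 center = center, current_mA = current_mA),
            class = "electrode_array_spec")
}

# skin height above y = 0 at medio-lateral position x (mm): the posterior
# surface of the trunk ellipse, posterior-most point at (0, 0)
skin_height <- function(torso, x) {
  a <- torso$major_axis / 2
  b <- torso$minor_axis / 2
  inside <- abs(x) < a
  y <- rep(NA_real_, length(x))
  y[inside] <- b * (1 - sqrt(1 - (x[inside] / a)^2))
  y
}

# check the kidney (plus capsule) fits inside the trunk; errors otherwise
validate_kidney_in_torso <- function(kidney, torso) {
  if (kidney$depth < torso$h_subc + torso$h_m)
    stop_geometry("kidney depth (", kidney$depth, " mm) places the kidney ",
                  "inside the body-wall layers (", torso$h_subc + torso$h_m,
                  " mm)")
  a <- torso$major_axis / 2
  b <- torso$minor_axis / 2
  sa <- kidney$semi_axes + kidney$capsule_margin  # capsule outer surface
  x0 <- kidney$lateral_offset
  ys <- skin_height(torso, x0)
  if (is.na(ys))
    stop_geometry("kidney lateral_offset lies outside the trunk ellipse")
  y0 <- ys + kidney$depth + kidney$semi_axes[3]
  th <- seq(0, pi, length.out = 25)
  ph <- seq(0, 2 * pi, length.out = 49)[-49]
  g <- expand.grid(th = th, ph = ph)
  px <- x0 + sa[2] * sin(g$th) * cos(g$ph)
  py <- y0 + sa[3] * sin(g$th) * sin(g$ph)
  pz <- sa[1] * cos(g$th)
  f <- (px / a)^2 + ((py - b) / b)^2
  if (any(f > 1))
    stop_geometry("kidney plus perirenal capsule extends outside the trunk ",
                  "ellipse")
  if (max(abs(pz)) > torso$axial_length / 2)
    stop_geometry("kidney plus capsule extends beyond the modelled trunk ",
                  "segment; increase axial_length")
  invisible(TRUE)
}

#' Move the kidney deeper or shallower
#'
#' Returns a copy of a kidney specification with a new skin-to-kidney depth,
#' all other fields unchanged. Used to emulate respiratory kidney
#' displacement (the kidney moves away from the skin during inhalation).
#'
#' @param kidney A [kidney_spec()].
#' @param depth New depth (mm).
#' @param torso Optional [torso_spec()]; when given, feasibility of the new
#'   placement is checked immediately.
#' @return A `kidney_spec` with the new depth.
#' @export
set_kidney_depth <- function(kidney, depth, torso = NULL) {
  stopifnot(inherits(kidney, "kidney_spec"))
  out <- kidney_spec(semi_axes = kidney$semi_axes, h_c = kidney$h_c,
                     depth = depth, lateral_offset = kidney$lateral_offset,
                     capsule_margin = kidney$capsule_margin)
  if (!is.null(torso)) validate_kidney_in_torso(out, torso)
  out
}

#' @export
print.torso_spec <- function(x, ...) {
  cat(sprintf(paste0("Trunk: ellipse %.1f x %.1f mm, wall %.2f mm fat + ",
                     "%.2f mm muscle, segment %.0f mm\n"),
              x$major_axis, x$minor_axis, x$h_subc, x$h_m, x$axial_length))
  invisible(x)
}

#' @export
print.kidney_spec <- function(x, ...) {
  cat(sprintf(paste0("Kidney: semi-axes (%g, %g, %g) mm, cortex %g mm, ",
                     "depth %g mm, offset %g mm, capsule %g mm\n"),
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3], x$h_c,
              x$depth, x$lateral_offset, x$capsule_margin))
  invisible(x)
}

#' @export
print.electrode_array_spec <- function(x, ...) {
  cat(sprintf(paste0("In-line tetrapolar array: spacing %g mm (current pair ",
                     "%g mm), disks %g mm, %g mA\n"),
              x$spacing, 3 * x$spacing, x$disk_diameter, x$current_mA))
  invisible(x)
}
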