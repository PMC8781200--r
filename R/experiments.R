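# In-silico measurement protocols: electrode-spacing sweep, kidney-depth
# sweep, and time-resolved pulsatile impedance synthesis.

model_id <- function(torso, kidney, tissues) {
  paste0("t", torso$major_axis, "x", torso$minor_axis,
         "w", torso$h_subc, "+", torso$h_m, "L", torso$axial_length,
         "_k", paste(kidney$semi_axes, collapse = "x"),
         "c", kidney$h_c, "d", kidney$depth, "o", kidney$lateral_offset,
         "m", kidney$capsule_margin,
         "_r", paste(signif(unclass(tissues), 4), collapse = ","))
}

case_list <- function(cases) {
  if (inherits(cases, "perfusion_case")) cases <- list(cases)
  cases <- lapply(cases, function(cs) {
    if (is.character(cs)) default_perfusion_cases()[[cs]] else cs
  })
  if (any(!vapply(cases, inherits, TRUE, "perfusion_case")))
    stop("cases must be perfusion_case objects or known case names")
  names(cases) <- vapply(cases, `[[`, "", "name")
  cases
}

#' Pulsatile impedance change
#'
#' The pulsatile (dynamic) impedance is the drop of the transfer impedance
#' from the baseline to the blood-filled state, `dZ = Z_before - Z_after`;
#' blood filling lowers kidney resistivity, so `dZ >= 0` for valid
#' perfusion cases.
#'
#' @param Z_before Baseline impedance (Ohm).
#' @param Z_after Blood-filled impedance (Ohm).
#' @return Impedance change (Ohm).
#' @export
dynamic_delta <- function(Z_before, Z_after) {
  if (any(!is.finite(Z_before)) || any(!is.finite(Z_after)))
    stop("impedances must be finite")
  Z_before - Z_after
}

solve_states <- function(grid, tissues, cases, tol, maxit = 1e5) {
  pattern <- stimulation_pattern(grid$footprints, grid$array$current_mA)
  tab_b <- apply_perfusion_case(tissues, cases[[1]], "before")
  Zb <- solve_tetrapolar(to_conductivity_field(grid, tab_b), pattern,
                         tol = tol, maxit = maxit)
  Za <- vapply(cases, function(cs) {
    tab_a <- apply_perfusion_case(tissues, cs, "after")
    solve_tetrapolar(to_conductivity_field(grid, tab_a), pattern,
                     tol = tol, maxit = maxit)
  }, numeric(1))
  list(Z_before = Zb, Z_after = Za)
}

#' Electrode-spacing sweep
#'
#' For each measuring-electrode spacing d, builds the array (current pair at
#' 3d), solves the baseline and every blood-filled perfusion state, and
#' tabulates the static impedance and the pulsatile change dZ. The default
#' spacing protocol is 7 to 40 mm in steps of 3 mm. Infeasible spacings
#' yield an `NA` row with a warning rather than aborting the sweep.
#'
#' @param torso,kidney Model specs ([torso_spec()], [kidney_spec()]).
#' @param tissues A [tissue_table()].
#' @param cases Perfusion cases (objects or names); default both reference
#'   cases.
#' @param d_values Measuring-electrode spacings (mm).
#' @param h Voxel size (mm); `NULL` adapts per row as `min(2, d/4)` so small
#'   spacings get finer surface resolution.
#' @param tol Solver tolerance.
#' @param current_mA Injected current (mA).
#' @return A data frame of class `sweep_table` with columns `d_mm`,
#'   `Z_before_ohm`, `Z_after_<case>_ohm` and `dZ_<case>_ohm`, sorted by d;
#'   attributes `h_mm` (per row) and `model_id`.
#' @export
spacing_sweep <- function(torso, kidney, tissues = tissue_table(),
                          cases = default_perfusion_cases(),
                          d_values = seq(7, 40, by = 3), h = NULL,
                          tol = 1e-8, current_mA = 3) {
  cases <- case_list(cases)
  d_values <- sort(d_values)
  h_row <- if (is.null(h)) pmin(2, d_values / 4) else rep(h, length(d_values))
  rows <- vector("list", length(d_values))
  for (i in seq_along(d_values)) {
    d <- d_values[i]
    res <- tryCatch({
      arr <- electrode_array_spec(spacing = d, current_mA = current_mA)
      grid <- build_patient_model(torso, kidney, arr, h = h_row[i])
      solve_states(grid, tissues, cases, tol)
    }, error = function(e) {
      warning("spacing d = ", d, " mm failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) {
      rows[[i]] <- c(rep(NA_real_, 1 + 2 * length(cases)))
    } else {
      rows[[i]] <- c(res$Z_before, res$Z_after,
                     dynamic_delta(res$Z_before, res$Z_after))
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("Z_before_ohm",
                  paste0("Z_after_", names(cases), "_ohm"),
                  paste0("dZ_", names(cases), "_ohm"))
  out <- cbind(d_mm = d_values, out)
  attr(out, "h_mm") <- h_row
  attr(out, "model_id") <- model_id(torso, kidney, tissues)
  class(out) <- c("sweep_table", class(out))
  out
}

#' Kidney-depth sweep
#'
#' Evaluates the pulsatile impedance at a fixed electrode spacing while the
#' kidney moves deeper (as it does during inhalation): sensitivity to renal
#' blood filling falls off with depth.
#'
#' @inheritParams spacing_sweep
#' @param case A single perfusion case (object or name).
#' @param depths Skin-to-kidney depths (mm).
#' @param d Measuring-electrode spacing (mm), fixed across depths.
#' @param h Voxel size (mm).
#' @return Data frame with columns `depth_mm`, `Z_before_ohm`,
#'   `Z_after_ohm`, `dZ_ohm`.
#' @export
depth_sweep <- function(torso, kidney, tissues = tissue_table(),
                        case = "90-10", depths, d = 20, h = 2,
                        tol = 1e-8, current_mA = 3) {
  cases <- case_list(list(case))
  depths <- sort(depths)
  rows <- vector("list", length(depths))
  for (i in seq_along(depths)) {
    rows[[i]] <- tryCatch({
      kid <- set_kidney_depth(kidney, depths[i], torso)
      arr <- electrode_array_spec(spacing = d, current_mA = current_mA)
      grid <- build_patient_model(torso, kid, arr, h = h)
      res <- solve_states(grid, tissues, cases, tol)
      c(res$Z_before, res$Z_after,
        dynamic_delta(res$Z_before, res$Z_after))
    }, error = function(e) {
      warning("depth ", depths[i], " mm failed: ", conditionMessage(e),
              call. = FALSE)
      rep(NA_real_, 3)
    })
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("Z_before_ohm", "Z_after_ohm", "dZ_ohm")
  out <- cbind(depth_mm = depths, out)
  attr(out, "h_mm") <- h
  attr(out, "model_id") <- model_id(torso, kidney, tissues)
  out
}

# blood mass (per 100 g) that reproduces a given resistivity drop through
# the parallel-conductor relation; inverse of parallel_conductor_delta
invert_parallel_delta <- function(delta, rho_k, rho_b, m_k = 100) {
  if (delta <= 0) return(0)
  if (delta >= rho_k - rho_b)
    stop("resistivity drop exceeds the parallel-conductor limit")
  m_k * rho_b * delta / (rho_k * (rho_k - rho_b - delta))
}

#' Time-resolved pulsatile impedance from a blood-volume curve
#'
#' Synthesizes the impedance waveform dZ(t) driven by the intrarenal
#' blood-volume curve Q(t). Layer blood masses are assumed proportional to
#' Q(t), scaled so that the cycle maximum reaches the perfusion case's
#' blood-filled resistivities; intermediate layer resistivities follow the
#' parallel-conductor relation. The forward problem is solved at
#' `n_keyframes` filling levels and dZ is interpolated in the filling
#' fraction between them. `n_keyframes = 2` degenerates to linear scaling,
#' `dZ(t) = dZ_max * Q(t) / max(Q)`, which is accurate because the
#' perturbation is small.
#'
#' @inheritParams spacing_sweep
#' @param case A single perfusion case (object or name).
#' @param Q A [blood_volume_change()] curve (cm^3 over one cardiac cycle).
#' @param d Measuring-electrode spacing (mm).
#' @param n_keyframes Number of solved filling levels (>= 2).
#' @param h Voxel size (mm).
#' @return An object of class `impedance_waveform`: data frame with
#'   `time_s` and `dz_mohm` (relative to the end-diastolic baseline,
#'   `dz_mohm[1] = 0` when `Q(0) = 0`).
#' @export
simulate_impedance_waveform <- function(torso, kidney, tissues = tissue_table(),
                                        case = "90-10", Q, d = 20,
                                        n_keyframes = 2, h = 2, tol = 1e-8,
                                        current_mA = 3) {
  stopifnot(inherits(Q, "blood_volume_curve"), n_keyframes >= 2)
  cases <- case_list(list(case))
  cs <- cases[[1]]
  if (any(Q$Q_cm3 < 0))
    stop("blood-volume curve must be non-negative relative to cycle start")
  qmax <- max(Q$Q_cm3)
  if (qmax == 0)
    return(structure(data.frame(time_s = Q$time_s, dz_mohm = 0 * Q$time_s),
                     class = c("impedance_waveform", "data.frame")))

  arr <- electrode_array_spec(spacing = d, current_mA = current_mA)
  grid <- build_patient_model(torso, kidney, arr, h = h)
  pattern <- stimulation_pattern(grid$footprints, current_mA)
  rho_b <- tissue_table()[["blood"]]

  # peak blood mass per layer implied by the case's blood-filled values
  m_max <- vapply(c("cortex", "medulla"), function(L) {
    invert_parallel_delta(cs$before[[L]] - cs$after[[L]], cs$before[[L]],
                          rho_b)
  }, numeric(1))

  f <- seq(0, 1, length.out = n_keyframes)
  Zf <- vapply(f, function(fr) {
    tab <- tissues
    for (L in c("cortex", "medulla")) {
      tab[[L]] <- cs$before[[L]] -
        parallel_conductor_delta(cs$before[[L]], rho_b, 100, fr * m_max[[L]])
    }
    solve_tetrapolar(to_conductivity_field(grid, tab), pattern, tol = tol)
  }, numeric(1))
  dZf <- Zf[1] - Zf  # Ohm, vs baseline

  frac <- Q$Q_cm3 / qmax
  dz <- stats::approx(f, dZf, xout = frac)$y * 1000  # mOhm
  structure(data.frame(time_s = Q$time_s, dz_mohm = dz),
            class = c("impedance_waveform", "data.frame"))
}
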