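# Tissue resistivities at 100 kHz and the parallel-conductor perfusion model.
#
# At 100 kHz the active (resistive) component dominates tissue impedance, so
# the model is purely resistive. Kidney cortex/medulla baseline resistivity
# is 5.84 Ohm*m; the remaining tissue values are literature-derived defaults
# (in-vitro measurements at 100 kHz), not measured for this subject, and are
# plain config values.

#' Default tissue resistivity table (100 kHz)
#'
#' Per-tissue electrical resistivity in Ohm*m. Kidney cortex and medulla
#' default to the baseline (pre-filling) value 5.84 Ohm*m; fat, muscle,
#' blood and abdominal background are literature values at 100 kHz and can
#' be overridden per patient.
#'
#' @param ... Named overrides, e.g. `muscle = 3.0`.
#' @return Named numeric vector of class `tissue_table` (Ohm*m) covering
#'   every conducting tissue label plus `blood`.
#' @export
tissue_table <- function(...) {
  tab <- c(subcutaneous_fat = 40, muscle = 2.8, perirenal_fat = 40,
           cortex = 5.84, medulla = 5.84, background = 5.0, blood = 1.5)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(tab))
    if (length(bad)) stop("unknown tissue(s): ", paste(bad, collapse = ", "))
    tab[names(over)] <- as.numeric(unlist(over))
  }
  if (any(tab <= 0) || any(!is.finite(tab)))
    stop("all resistivities must be positive and finite")
  structure(tab, class = "tissue_table")
}

#' Resistivity decrease of blood-filled tissue (parallel-conductor model)
#'
#' Tissue of mass `m_k` and resistivity `rho_k` receiving an added blood
#' mass `m_b` of resistivity `rho_b` is modelled as two conductors in
#' parallel, giving a resistivity decrease
#' `delta = rho_k * m_b * (rho_k - rho_b) / (m_k * rho_b + m_b * rho_k)`,
#' so the blood-filled resistivity is `rho_k - delta`.
#'
#' @param rho_k Tissue resistivity (Ohm*m).
#' @param rho_b Blood resistivity (Ohm*m).
#' @param m_k Tissue mass (g).
#' @param m_b Added blood mass (g); same mass basis as `m_k`.
#' @return Resistivity decrease (Ohm*m); zero when `m_b = 0` or
#'   `rho_k = rho_b`.
#' @export
parallel_conductor_delta <- function(rho_k, rho_b, m_k, m_b) {
  if (any(rho_k <= 0) || any(rho_b <= 0) || any(m_k <= 0) || any(m_b < 0) ||
      any(!is.finite(c(rho_k, rho_b, m_k, m_b))))
    stop("rho_k, rho_b, m_k must be positive and m_b non-negative")
  rho_k * m_b * (rho_k - rho_b) / (m_k * rho_b + m_b * rho_k)
}

#' Blood mass delivered per cardiac cycle
#'
#' Converts a specific perfusion rate (mL per minute per 100 g of tissue)
#' into the blood mass delivered over one cardiac cycle, per 100 g of
#' tissue — the `m_b` of the parallel-conductor model with `m_k = 100` g.
#'
#' @param flow_per_100g Perfusion rate (mL/min per 100 g); a healthy kidney
#'   receives roughly 400.
#' @param cycle_duration Cardiac cycle length (s), default 1.
#' @param blood_density Blood density (g/mL), default 1.05.
#' @return Blood mass per cycle (g per 100 g of tissue).
#' @export
blood_mass_per_cycle <- function(flow_per_100g, cycle_duration = 1,
                                 blood_density = 1.05) {
  if (any(flow_per_100g < 0) || any(cycle_duration <= 0) ||
      any(blood_density <= 0))
    stop("flow must be non-negative; cycle duration and density positive")
  flow_per_100g / 60 * cycle_duration * blood_density
}

#' Renal blood-distribution (perfusion) case
#'
#' A perfusion case fixes the cortex/medulla split of renal blood flow and
#' the resulting layer resistivities before and after blood filling. In
#' normal perfusion the cortex receives about 90% of renal flow.
#'
#' @param name Case identifier, e.g. `"90-10"`.
#' @param cortex_blood_fraction Fraction of renal blood flow to the cortex,
#'   in (0, 1]; the medulla receives the rest.
#' @param after Named vector `c(cortex=, medulla=)` of blood-filled
#'   resistivities (Ohm*m).
#' @param before Named vector of baseline resistivities (Ohm*m); defaults to
#'   5.84 for both layers.
#' @return An object of class `perfusion_case`.
#' @export
perfusion_case <- function(name, cortex_blood_fraction, after,
                           before = c(cortex = 5.84, medulla = 5.84)) {
  stopifnot(is.character(name), length(name) == 1)
  if (cortex_blood_fraction <= 0 || cortex_blood_fraction > 1)
    stop("cortex_blood_fraction must lie in (0, 1]")
  for (v in list(after, before))
    if (!all(c("cortex", "medulla") %in% names(v)) || any(v <= 0))
      stop("after/before need positive 'cortex' and 'medulla' entries")
  if (any(after[c("cortex", "medulla")] > before[c("cortex", "medulla")]))
    stop("blood filling cannot increase layer resistivity (after > before)")
  structure(list(name = name,
                 cortex_blood_fraction = cortex_blood_fraction,
                 after = after[c("cortex", "medulla")],
                 before = before[c("cortex", "medulla")]),
            class = "perfusion_case")
}

#' The two reference perfusion cases
#'
#' Normal perfusion (90% of renal flow to the cortex) and reduced cortical
#' perfusion (70%), with the corresponding blood-filled layer resistivities;
#' baseline is 5.84 Ohm*m for both layers.
#'
#' @return Named list of two [perfusion_case()] objects, `"90-10"` and
#'   `"70-30"`.
#' @export
default_perfusion_cases <- function() {
  list(
    "90-10" = perfusion_case("90-10", 0.9,
                             after = c(cortex = 4.99, medulla = 5.75)),
    "70-30" = perfusion_case("70-30", 0.7,
                             after = c(cortex = 5.18, medulla = 5.56))
  )
}

#' Apply a perfusion case to a tissue table
#'
#' Replaces the cortex and medulla resistivities with the case's baseline
#' (`"before"`) or blood-filled (`"after"`) values; all other tissues are
#' unchanged. Idempotent for a fixed (case, state).
#'
#' @param table A [tissue_table()].
#' @param case A [perfusion_case()], or a name looked up in
#'   [default_perfusion_cases()].
#' @param state `"before"` or `"after"` blood filling.
#' @return A modified `tissue_table`.
#' @export
apply_perfusion_case <- function(table, case, state = c("after", "before")) {
  stopifnot(inherits(table, "tissue_table"))
  state <- match.arg(state)
  if (is.character(case)) {
    cases <- default_perfusion_cases()
    if (!case %in% names(cases))
      stop("unknown perfusion case '", case, "'")
    case <- cases[[case]]
  }
  stopifnot(inherits(case, "perfusion_case"))
  vals <- if (state == "after") case$after else case$before
  table[["cortex"]] <- vals[["cortex"]]
  table[["medulla"]] <- vals[["medulla"]]
  table
}

#' Per-voxel conductivity field
#'
#' Converts a tissue label grid and a resistivity table into the per-voxel
#' conductivity (S/m) used by the forward solver; `outside` voxels carry
#' conductivity 0 and are excluded from the conduction domain.
#'
#' @param grid A `label_grid`.
#' @param table A [tissue_table()] covering every label present in the grid.
#' @return An object of class `conductivity_field`: grid metadata plus the
#'   3-D numeric array `sigma` (S/m).
#' @export
to_conductivity_field <- function(grid, table) {
  stopifnot(inherits(grid, "label_grid"), inherits(table, "tissue_table"))
  lv <- tissue_levels()
  present <- lv[sort(unique(as.integer(grid$labels))) + 1L]
  present <- setdiff(present, "outside")
  missing <- setdiff(present, names(table))
  if (length(missing))
    stop("tissue table lacks resistivity for: ",
         paste(missing, collapse = ", "))
  sig_by_code <- c(0, 1 / unname(table[lv[-1]]))  # S/m; outside -> 0
  sig_by_code[is.na(sig_by_code)] <- 0
  sigma <- array(sig_by_code[as.integer(grid$labels) + 1L], dim = grid$dims)
  structure(list(h = grid$h, dims = grid$dims, origin = grid$origin,
                 sigma = sigma, grid = grid),
            class = "conductivity_field")
}

#' @export
print.tissue_table <- function(x, ...) {
  cat("Tissue resistivities at 100 kHz (Ohm*m):\n")
  print(unclass(x))
  invisible(x)
}
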