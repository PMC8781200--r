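# Doppler-derived renal blood-volume change and its correlation against the
# impedance waveform. The per-cycle kidney blood-volume change is the
# running difference of arterial volumetric inflow and venous outflow,
# Q(t) = int_0^t Va*Sa dt - int_0^t Vv*Sv dt, integrated by the trapezoid
# rule (exact for piecewise-linear velocity traces).

uniform_dt <- function(time, what = "time base") {
  if (length(time) < 2 || any(diff(time) <= 0))
    stop(what, " must be strictly increasing with >= 2 samples")
  dt <- diff(time)
  if (diff(range(dt)) > 1e-8 * max(dt))
    stop(what, " must be uniform; resample first (see align_and_resample)")
  dt[1]
}

#' Doppler velocity waveform
#'
#' One cardiac cycle of a (spatially averaged) blood-velocity trace in the
#' renal artery or vein, with the vessel's lumen cross-section. The
#' reference cross-sections are 0.30 cm^2 (artery) and 0.38 cm^2 (vein).
#'
#' @param time Sample times (s), uniform and strictly increasing.
#' @param velocity Velocity (cm/s); must be non-negative for an artery.
#' @param S Vessel cross-sectional area (cm^2).
#' @param role `"artery"` or `"vein"`.
#' @return A data frame of class `velocity_waveform` with columns `time_s`,
#'   `velocity_cm_s` and attributes `S_cm2`, `role`.
#' @export
velocity_waveform <- function(time, velocity, S, role = c("artery", "vein")) {
  role <- match.arg(role)
  if (length(time) != length(velocity))
    stop("time and velocity must have equal length")
  uniform_dt(time)
  if (S <= 0) stop("vessel cross-section S must be positive")
  if (role == "artery" && any(velocity < 0))
    stop("arterial velocity must be non-negative")
  structure(data.frame(time_s = time, velocity_cm_s = velocity),
            S_cm2 = S, role = role,
            class = c("velocity_waveform", "data.frame"))
}

#' Volumetric flow from a velocity waveform
#'
#' Pointwise flow = velocity x cross-section.
#'
#' @param w A [velocity_waveform()].
#' @return Data frame with `time_s` and `flow_cm3_s`, attribute `role`.
#' @export
volumetric_flow <- function(w) {
  stopifnot(inherits(w, "velocity_waveform"))
  structure(data.frame(time_s = w$time_s,
                       flow_cm3_s = w$velocity_cm_s * attr(w, "S_cm2")),
            role = attr(w, "role"),
            class = c("flow_curve", "data.frame"))
}

#' Kidney blood-volume change over one cardiac cycle
#'
#' Integrates the arterio-venous flow difference from cycle start:
#' `Q(t)` is the cumulative (trapezoid-rule) integral of arterial inflow
#' minus venous outflow, with `Q(0) = 0`. Balanced flows give `Q == 0`.
#'
#' @param artery_flow,vein_flow Flow curves from [volumetric_flow()] on a
#'   common uniform time base.
#' @return A data frame of class `blood_volume_curve` with `time_s` and
#'   `Q_cm3`.
#' @export
blood_volume_change <- function(artery_flow, vein_flow) {
  stopifnot(inherits(artery_flow, "flow_curve"),
            inherits(vein_flow, "flow_curve"))
  if (nrow(artery_flow) != nrow(vein_flow) ||
      max(abs(artery_flow$time_s - vein_flow$time_s)) >
        1e-9 * max(abs(artery_flow$time_s), 1))
    stop("artery and vein flows must share the same time base")
  uniform_dt(artery_flow$time_s)
  diff_flow <- artery_flow$flow_cm3_s - vein_flow$flow_cm3_s
  Q <- pracma::cumtrapz(artery_flow$time_s, diff_flow)[, 1]
  structure(data.frame(time_s = artery_flow$time_s, Q_cm3 = Q),
            class = c("blood_volume_curve", "data.frame"))
}

#' Align two time series on a common uniform grid
#'
#' Linearly interpolates both series onto a shared uniform grid covering the
#' overlap of their time supports, at the given sampling rate (default
#' 500 Hz, the impedance acquisition rate).
#'
#' @param x,y Data frames whose first column is time (s) and second the
#'   value.
#' @param rate Sampling rate (Hz).
#' @return List with `time`, `x`, `y` (equal-length numeric vectors).
#' @export
align_and_resample <- function(x, y, rate = 500) {
  chk_pos(rate, "rate")
  tx <- x[[1]]; ty <- y[[1]]
  t0 <- max(min(tx), min(ty))
  t1 <- min(max(tx), max(ty))
  if (t0 >= t1) stop("time supports do not overlap")
  time <- seq(t0, t1, by = 1 / rate)
  list(time = time,
       x = stats::approx(tx, x[[2]], xout = time)$y,
       y = stats::approx(ty, y[[2]], xout = time)$y)
}

#' Correlation between blood volume and impedance waveforms
#'
#' Sample Pearson correlation between the Doppler-derived blood-volume
#' curve and the impedance waveform over one cardiac cycle, after alignment
#' on a common grid. This is the verification statistic tying the impedance
#' signal to renal blood filling.
#'
#' @param Q A [blood_volume_change()] curve (or any time/value data frame).
#' @param dz An impedance waveform (time/value data frame).
#' @param rate Resampling rate (Hz) when the time bases differ; series
#'   already on a common base are used as is.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(Q, dz, rate = 500) {
  if (nrow(Q) == nrow(dz) &&
      isTRUE(max(abs(Q[[1]] - dz[[1]])) <= 1e-9 * max(abs(Q[[1]]), 1))) {
    a <- Q[[2]]; b <- dz[[2]]
  } else {
    al <- align_and_resample(Q, dz, rate = rate)
    a <- al$x; b <- al$y
  }
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("need at least 3 aligned samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: one series has zero variance")
  stats::cor(a, b)
}
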