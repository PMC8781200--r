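# Synthetic inputs: Doppler-like velocity waveform pair, impedance waveform
# with known ground truth, and the reference patient fixture. All generators
# are deterministic for a fixed seed, and changing only the seed changes
# only the noise realization.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic Doppler waveform parameters
#'
#' Parameters of the renal artery/vein velocity generator. The defaults are
#' chosen so the per-cycle arterial volume matches the renal stroke volume
#' implied by a healthy perfusion of 400 mL/min per 100 g scaled to a 130 g
#' kidney at a 1 s cycle (about 8.7 cm^3 through a 0.30 cm^2 artery):
#' diastolic floor 18 cm/s, systolic peak 67 cm/s over 35% of the cycle.
#'
#' @param cycle_T Cardiac cycle length (s).
#' @param peak_velocity Arterial systolic peak velocity (cm/s).
#' @param systolic_fraction Fraction of the cycle occupied by the systolic
#'   half-sine, in `[0, 1]`.
#' @param diastolic_floor Arterial diastolic velocity (cm/s).
#' @param vein_mean Mean venous velocity (cm/s); the default balances the
#'   arterial cycle volume through the 0.38 cm^2 vein.
#' @param vein_pulsatility Relative venous modulation amplitude, in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise, as a fraction of each signal's
#'   standard deviation.
#' @param seed Integer seed for the noise; `NULL` leaves the RNG alone.
#' @return A list of class `waveform_params`.
#' @export
waveform_params <- function(cycle_T = 1, peak_velocity = 67,
                            systolic_fraction = 0.35, diastolic_floor = 18,
                            vein_mean = 22.8, vein_pulsatility = 0.3,
                            noise_sd = 0, seed = NULL) {
  chk_pos(cycle_T, "cycle_T")
  if (systolic_fraction < 0 || systolic_fraction > 1 ||
      vein_pulsatility < 0 || vein_pulsatility > 1)
    stop("fractions must lie in [0, 1]")
  if (peak_velocity < 0 || diastolic_floor < 0 || vein_mean < 0 ||
      noise_sd < 0)
    stop("velocities and noise_sd must be non-negative")
  if (peak_velocity < diastolic_floor)
    stop("peak velocity below the diastolic floor")
  structure(list(cycle_T = cycle_T, peak_velocity = peak_velocity,
                 systolic_fraction = systolic_fraction,
                 diastolic_floor = diastolic_floor, vein_mean = vein_mean,
                 vein_pulsatility = vein_pulsatility, noise_sd = noise_sd,
                 seed = seed),
            class = "waveform_params")
}

#' Generate a synthetic renal artery/vein velocity pair
#'
#' Artery: diastolic floor plus a half-sine systolic peak over the systolic
#' fraction of the cycle. Vein: mean velocity with sinusoidal modulation.
#' Optional additive Gaussian noise (seeded); arterial samples are clamped
#' at zero so the waveform stays physical.
#'
#' @param p A [waveform_params()].
#' @param rate Sampling rate (Hz), default 500.
#' @param S_a,S_v Artery / vein cross-sections (cm^2).
#' @return List with `artery` and `vein` [velocity_waveform()]s.
#' @export
synth_velocity_pair <- function(p = waveform_params(), rate = 500,
                                S_a = 0.30, S_v = 0.38) {
  stopifnot(inherits(p, "waveform_params"))
  chk_pos(rate, "rate")
  Ts <- p$systolic_fraction * p$cycle_T
  if (Ts > 0 && rate * Ts < 20)
    stop("sampling rate too low to resolve the systolic peak ",
         "(need >= 20 samples)")
  time <- seq(0, p$cycle_T, by = 1 / rate)
  va <- rep(p$diastolic_floor, length(time))
  sys <- time < Ts
  va[sys] <- p$diastolic_floor +
    (p$peak_velocity - p$diastolic_floor) * sin(pi * time[sys] / Ts)
  vv <- p$vein_mean * (1 + p$vein_pulsatility * sin(2 * pi * time / p$cycle_T))
  if (p$noise_sd > 0) {
    noise <- with_seed(p$seed, list(a = stats::rnorm(length(time)),
                                    v = stats::rnorm(length(time))))
    va <- pmax(0, va + p$noise_sd * stats::sd(va) * noise$a)
    vv <- pmax(0, vv + p$noise_sd * stats::sd(vv) * noise$v)
  }
  list(artery = velocity_waveform(time, va, S_a, "artery"),
       vein = velocity_waveform(time, vv, S_v, "vein"))
}

#' Synthetic impedance waveform from a blood-volume curve
#'
#' Generates an impedance waveform with known ground truth,
#' `dz(t) = gain * Q(t) + noise`, for testing the volume/impedance
#' correlation pipeline end to end.
#'
#' @param Q A [blood_volume_change()] curve.
#' @param gain Impedance sensitivity to blood volume (mOhm per cm^3).
#' @param noise_sd Absolute Gaussian noise standard deviation (mOhm).
#' @param seed Integer seed; `NULL` leaves the RNG alone.
#' @return An `impedance_waveform` data frame (`time_s`, `dz_mohm`).
#' @export
synth_impedance_from_volume <- function(Q, gain = 1, noise_sd = 0,
                                        seed = NULL) {
  stopifnot(inherits(Q, "blood_volume_curve"))
  chk_pos(gain, "gain")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  dz <- gain * Q$Q_cm3
  if (noise_sd > 0)
    dz <- dz + with_seed(seed, stats::rnorm(length(dz), sd = noise_sd))
  structure(data.frame(time_s = Q$time_s, dz_mohm = dz),
            class = c("impedance_waveform", "data.frame"))
}

#' Reference patient fixture
#'
#' The default patient model: trunk ellipse 253.7 x 166.71 mm with 5.54 mm
#' subcutaneous fat and 10.74 mm muscle; two-layer kidney with 5 mm cortex;
#' reference tissue resistivities and both perfusion cases (90-10 and
#' 70-30). Kidney semi-axes, depth, lateral offset and capsule thickness are
#' typical-anatomy defaults, overridable through the specs.
#'
#' @return List with elements `torso`, `kidney`, `tissues`, `cases`.
#' @export
default_patient <- function() {
  list(torso = torso_spec(), kidney = kidney_spec(),
       tissues = tissue_table(), cases = default_perfusion_cases())
}
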