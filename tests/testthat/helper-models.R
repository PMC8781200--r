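# Small fixtures used across tests: a scaled-down trunk/kidney model whose
# forward solves run in well under a second, and a homogeneous block.

tiny_torso <- function(axial = 120) {
  torso_spec(major_axis = 120, minor_axis = 90, h_subc = 5.54, h_m = 10.74,
             axial_length = axial)
}

tiny_kidney <- function(depth = 20, lateral_offset = 20) {
  kidney_spec(semi_axes = c(20, 12, 8), h_c = 4, depth = depth,
              lateral_offset = lateral_offset, capsule_margin = 5)
}

tiny_model <- function(d = 12, h = 4, depth = 20, lateral_offset = 20) {
  build_patient_model(tiny_torso(), tiny_kidney(depth, lateral_offset),
                      electrode_array_spec(spacing = d), h = h)
}

# hand-built conductivity field (bypasses label grids) for stencil tests
raw_field <- function(sigma, h = 1) {
  structure(list(h = h, dims = dim(sigma), origin = c(0, 0, 0),
                 sigma = sigma, grid = NULL),
            class = "conductivity_field")
}

# half-sine systolic artery velocity over [0, Ts], floor elsewhere
half_sine_velocity <- function(time, peak, Ts, floor = 0) {
  v <- rep(floor, length(time))
  sys <- time < Ts
  v[sys] <- floor + (peak - floor) * sin(pi * time[sys] / Ts)
  v
}
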