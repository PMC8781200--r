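test_that("assembled operator has conservative stencil rows and harmonic-mean
           faces", {
  sig <- array(1, dim = c(3, 3, 3))
  sig[2, 1, 1] <- 3  # one contrasting voxel
  f <- raw_field(sig, h = 1)
  pat <- stimulation_pattern(list(C1 = 1L, M1 = 5L, M2 = 23L, C2 = 27L))
  sys <- assemble_conduction_system(f, pat)
  m <- conduction_matrix(sys)
  expect_true(Matrix::isSymmetric(m$A))
  # pure-Neumann operator: every row sums to zero (charge conservation)
  expect_lt(max(abs(Matrix::rowSums(m$A))), 1e-12)
  # face between sigma = 1 and sigma = 3 uses the harmonic mean 1.5
  h_m <- 1 / 1000
  expect_equal(m$A[1, 2], -h_m * 1.5)
  # right-hand side sums to zero
  expect_equal(sum(m$b), 0)
})

test_that("solved potential on a homogeneous bar is linear", {
  n <- 12
  sig <- array(0.5, dim = c(1, 1, n))
  f <- raw_field(sig, h = 2)
  pat <- stimulation_pattern(list(C1 = 1L, M1 = 4L, M2 = 9L, C2 = n),
                             current_mA = 3)
  phi <- solve_potential(assemble_conduction_system(f, pat), tol = 1e-12)
  p <- as.numeric(phi$phi)
  # interior links all carry the same current: equal consecutive drops
  drops <- diff(p)
  expect_lt(max(abs(drops - drops[1])), 1e-6 * abs(drops[1]))
  # Z equals the link-chain resistance between the pick-up voxels
  Z <- transfer_impedance(phi, pat)
  g_link <- 0.5 * 2 / 1000  # sigma * h_m
  expect_equal(Z, (9 - 4) / g_link, tolerance = 1e-9)
  # sign convention: M1 nearer the source C1 gives positive Z
  pat2 <- stimulation_pattern(list(C1 = 1L, M1 = 4L, M2 = 9L, C2 = n))
  expect_gt(transfer_impedance(phi, pat2), 0)
})

test_that("solution scales inversely with conductivity and is
           current-independent in Z", {
  g <- block_grid(40, 24, 40, h = 4)
  fp <- place_electrode_array(g, electrode_array_spec(spacing = 10))
  pat1 <- stimulation_pattern(fp, current_mA = 3)
  f1 <- to_conductivity_field(g, tissue_table(background = 5))
  f2 <- to_conductivity_field(g, tissue_table(background = 5 / 3))
  Z1 <- solve_tetrapolar(f1, pat1, tol = 1e-10)
  Z2 <- solve_tetrapolar(f2, pat1, tol = 1e-10)
  expect_equal(Z2, Z1 / 3, tolerance = 1e-7)
  pat2 <- stimulation_pattern(fp, current_mA = 6)
  expect_equal(solve_tetrapolar(f1, pat2, tol = 1e-10), Z1,
               tolerance = 1e-7)
})

test_that("coincident pick-up electrodes read zero", {
  g <- block_grid(40, 24, 40, h = 4)
  fp <- place_electrode_array(g, electrode_array_spec(spacing = 10))
  f <- to_conductivity_field(g, tissue_table(background = 5))
  phi <- solve_potential(assemble_conduction_system(
    f, stimulation_pattern(fp)))
  pat_same <- structure(list(C1 = fp$C1, M1 = fp$M1, M2 = fp$M1, C2 = fp$C2,
                             current_mA = 3),
                        class = "stimulation_pattern")
  expect_equal(transfer_impedance(phi, pat_same), 0)
})

test_that("matrix-free CG agrees with a direct sparse solve", {
  set.seed(42)
  sig <- array(exp(stats::rnorm(6 * 5 * 7, sd = 0.5)), dim = c(6, 5, 7))
  sig[1, 3, 2] <- 0  # a hole outside the conduction domain
  f <- raw_field(sig, h = 2)
  pat <- stimulation_pattern(list(C1 = 2L, M1 = 65L, M2 = 120L, C2 = 208L))
  sys <- assemble_conduction_system(f, pat)
  phi <- solve_potential(sys, tol = 1e-12)
  m <- conduction_matrix(sys)
  # direct solve with one node grounded, then re-gauged to zero mean
  n <- nrow(m$A)
  Ar <- m$A[-n, -n]
  xr <- Matrix::solve(Ar, m$b[-n])
  x <- c(as.numeric(xr), 0)
  x <- x - mean(x)
  expect_equal(as.numeric(phi$phi)[m$index], x, tolerance = 1e-8)
})

test_that("analytic tetrapolar formula evaluates and validates", {
  # Wenner reduction: a = 1.5 d, b = 0.5 d gives rho / (2 pi d)
  expect_equal(analytic_tetrapolar(2 * pi, 1.5, 0.5), 1)
  expect_equal(analytic_tetrapolar(5.84, 0.03, 0.01), 46.48, tolerance = 1e-3)
  expect_equal(analytic_tetrapolar(5, 0.03, 0), 0)
  expect_error(analytic_tetrapolar(5, 0.01, 0.03), "a > b")
  expect_error(analytic_tetrapolar(-5, 0.03, 0.01), "positive")
})

test_that("box image reference reduces to the half-space formula for a large
           box", {
  Z_inf <- analytic_tetrapolar(5, 0.03, 0.01)
  Z_box <- analytic_tetrapolar_box(5, width = 3, depth = 1.5, length = 3,
                                   C1 = c(0, -0.03), M1 = c(0, -0.01),
                                   M2 = c(0, 0.01), C2 = c(0, 0.03))
  expect_equal(Z_box, Z_inf, tolerance = 2e-3)
})

test_that("solved block impedance approaches the half-space value", {
  # modest block: lateral extent 5x the current-electrode span
  g <- block_grid(width = 152, depth = 60, length = 152, h = 2)
  fp <- place_electrode_array(g, electrode_array_spec(spacing = 10))
  f <- to_conductivity_field(g, tissue_table(background = 5))
  Z <- solve_tetrapolar(f, stimulation_pattern(fp))
  Zan <- analytic_tetrapolar(5, 0.015, 0.005)
  expect_lt(abs(Z - Zan) / Zan, 0.05)
})

test_that("reciprocity holds on homogeneous and heterogeneous models", {
  g <- block_grid(60, 32, 60, h = 4)
  fp <- place_electrode_array(g, electrode_array_spec(spacing = 12))
  f <- to_conductivity_field(g, tissue_table(background = 5))
  rec <- reciprocity_error(f, stimulation_pattern(fp), tol = 1e-10)
  expect_lt(rec$error, 1e-6)
  gm <- tiny_model()
  fm <- to_conductivity_field(gm, tissue_table())
  recm <- reciprocity_error(fm, stimulation_pattern(gm$footprints),
                            tol = 1e-8)
  expect_lt(recm$error, 1e-3)
})

test_that("swapped-pair pattern with shared footprints is rejected", {
  expect_error(stimulation_pattern(list(C1 = 1L, M1 = 1L, M2 = 5L, C2 = 9L)),
               "disjoint")
})

test_that("mirror-symmetric model yields antisymmetric pick-up potentials", {
  g <- build_patient_model(tiny_torso(), tiny_kidney(lateral_offset = 0),
                           electrode_array_spec(spacing = 12,
                                                center = c(0, 0)), h = 4)
  f <- to_conductivity_field(g, tissue_table())
  pat <- stimulation_pattern(g$footprints)
  phi <- solve_potential(assemble_conduction_system(f, pat), tol = 1e-11)
  v1 <- mean(phi$phi[pat$M1]); v2 <- mean(phi$phi[pat$M2])
  expect_lt(abs(v1 + v2), 1e-7 * abs(v1))
})

test_that("repeated solves are bit-identical", {
  g <- block_grid(40, 24, 40, h = 4)
  fp <- place_electrode_array(g, electrode_array_spec(spacing = 10))
  f <- to_conductivity_field(g, tissue_table(background = 5))
  Z1 <- solve_tetrapolar(f, stimulation_pattern(fp))
  Z2 <- solve_tetrapolar(f, stimulation_pattern(fp))
  expect_identical(Z1, Z2)
})

test_that("a higher-resistivity slab between electrodes and interior raises
           impedance", {
  g <- block_grid(80, 40, 80, h = 4)
  fp <- place_electrode_array(g, electrode_array_spec(spacing = 12))
  pat <- stimulation_pattern(fp)
  f1 <- to_conductivity_field(g, tissue_table(background = 5))
  # insert an insulating-ish slab at 8-16 mm depth
  f2 <- f1
  f2$sigma[, 3:4, ] <- 1 / 40
  Z1 <- solve_tetrapolar(f1, pat)
  Z2 <- solve_tetrapolar(f2, pat)
  expect_gt(Z2, Z1)
})
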