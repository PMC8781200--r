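test_that("spec constructors validate their invariants", {
  expect_s3_class(torso_spec(), "torso_spec")
  expect_error(torso_spec(h_subc = 50, h_m = 40), "thinner")
  expect_error(torso_spec(minor_axis = -1), "positive")
  expect_error(kidney_spec(h_c = 20, semi_axes = c(45, 25, 15)), "smallest")
  expect_error(electrode_array_spec(spacing = 2, disk_diameter = 3),
               "overlap")
  # kidney deeper than the trunk allows
  expect_error(build_patient_model(tiny_torso(),
                                   tiny_kidney(depth = 80),
                                   electrode_array_spec(spacing = 12), h = 4),
               "outside|segment|layers")
  # kidney inside the body-wall layers
  expect_error(tiny_model(depth = 10), "layers")
})

test_that("voxel size coarser than the cortex shell is refused", {
  expect_error(build_patient_model(tiny_torso(), tiny_kidney(),
                                   electrode_array_spec(spacing = 12), h = 5),
               "unresolvable")
})

test_that("layer order along the electrode normal is fat, muscle, interior", {
  g <- tiny_model()
  fp <- g$footprints
  ai <- arrayInd(fp$M1[1], g$dims)
  col <- g$labels[ai[1], , ai[3]]
  lv <- tissue_levels()
  inb <- which(col != 0)
  prof <- lv[col[inb] + 1L]
  # first fat, then muscle, then something deeper (background/capsule/kidney)
  expect_equal(prof[1], "subcutaneous_fat")
  runs <- rle(prof)$values
  expect_equal(runs[1:2], c("subcutaneous_fat", "muscle"))
  expect_true(all(c("cortex", "medulla") %in% prof))
  # fat slab thickness ceiling(h_subc / h) +- 1 voxel of rasterization
  n_fat <- sum(prof == "subcutaneous_fat")
  expect_gte(n_fat, 1)
  expect_lte(n_fat, ceiling(5.54 / g$h) + 1)
})

test_that("every in-trunk voxel gets exactly one label and the total volume
           matches the elliptic cylinder", {
  g <- tiny_model()
  v <- tissue_volumes(g)
  a <- 60; b <- 45; L <- tiny_torso()$axial_length
  v_analytic <- pi * a * b * L
  v_in <- sum(v) - v[["outside"]]
  # surface rasterization bound: one voxel layer on the lateral surface
  bound <- pi * (a + b) * L * g$h
  expect_lt(abs(v_in - v_analytic), bound)
})

test_that("cortex voxel volume approximates the ellipsoid-shell closed form", {
  # shell volume 4/3 pi [abc - (a-hc)(b-hc)(c-hc)] at h = 1 mm within 10%
  torso <- torso_spec(axial_length = 160)
  kid <- kidney_spec()  # semi-axes (45, 25, 15), h_c = 5
  g <- build_patient_model(torso, kid, electrode_array_spec(spacing = 20),
                           h = 1)
  v <- tissue_volumes(g)
  s <- kid$semi_axes
  v_shell <- 4 / 3 * pi * (prod(s) - prod(s - kid$h_c))
  expect_lt(abs(v[["cortex"]] - v_shell) / v_shell, 0.10)
  v_inner <- 4 / 3 * pi * prod(s - kid$h_c)
  expect_lt(abs(v[["medulla"]] - v_inner) / v_inner, 0.10)
})

test_that("electrode footprints are collinear, correctly spaced and on skin", {
  g <- tiny_model(d = 12, h = 4)
  ctr <- attr(g$footprints, "centers")
  expect_equal(unname(diff(ctr)), c(12, 12, 12))
  expect_equal(unname(ctr[["C2"]] - ctr[["C1"]]), 3 * 12)
  expect_true(all(lengths(g$footprints) >= 1))
  # footprints sit on the surface voxel of their column
  for (idx in g$footprints) {
    ai <- arrayInd(idx, g$dims)
    expect_true(all(g$surf_iy[ai[, 1]] == ai[, 2]))
  }
})

test_that("disk rasterization at h = 1 mm yields about pi r^2 faces", {
  g <- block_grid(width = 61, depth = 20, length = 81, h = 1)
  fp <- place_electrode_array(g, electrode_array_spec(spacing = 20))
  # pi * 1.5^2 / 1 = 7.07 faces, +- 2 from staircase effects
  for (idx in fp) expect_true(abs(length(idx) - 7) <= 2)
})

test_that("array that falls off the grid raises a placement error", {
  g <- block_grid(width = 60, depth = 20, length = 60, h = 2)
  expect_error(place_electrode_array(g, electrode_array_spec(spacing = 25)),
               "off the grid")
})

test_that("set_kidney_depth shifts kidney labels along the normal", {
  g1 <- tiny_model(depth = 20, h = 4)
  kid2 <- set_kidney_depth(tiny_kidney(depth = 20), 28, tiny_torso())
  expect_equal(kid2$depth, 28)
  expect_equal(kid2$semi_axes, tiny_kidney()$semi_axes)
  g2 <- build_patient_model(tiny_torso(), kid2,
                            electrode_array_spec(spacing = 12), h = 4)
  kid_codes <- match(c("cortex", "medulla"), tissue_levels()) - 1L
  a1 <- arrayInd(which(g1$labels %in% kid_codes), g1$dims)
  a2 <- arrayInd(which(g2$labels %in% kid_codes), g2$dims)
  a1[, 2] <- a1[, 2] + 8 / 4  # 8 mm deeper = 2 voxels along +y
  expect_equal(a2[order(a2[, 1], a2[, 2], a2[, 3]), ],
               a1[order(a1[, 1], a1[, 2], a1[, 3]), ])
})

test_that("identical depth gives an identical model", {
  g1 <- tiny_model()
  kid <- set_kidney_depth(tiny_kidney(), tiny_kidney()$depth)
  g2 <- build_patient_model(tiny_torso(), kid,
                            electrode_array_spec(spacing = 12), h = 4)
  expect_identical(g1$labels, g2$labels)
})

test_that("centred model is mirror-symmetric about the electrode plane", {
  g <- build_patient_model(tiny_torso(), tiny_kidney(lateral_offset = 0),
                           electrode_array_spec(spacing = 12,
                                                center = c(0, 0)),
                           h = 4)
  nx <- g$dims[1]
  expect_identical(g$labels, g$labels[nx:1, , ])
})

test_that("per-tissue volumes are stable under grid refinement", {
  g4 <- tiny_model(h = 4)
  g2 <- tiny_model(h = 2)
  v4 <- tissue_volumes(g4); v2 <- tissue_volumes(g2)
  for (tis in c("muscle", "cortex", "medulla", "background"))
    expect_lt(abs(v4[[tis]] - v2[[tis]]) / v2[[tis]], 0.25)
})

test_that("footprint_coords reports physical surface positions", {
  g <- block_grid(width = 60, depth = 20, length = 80, h = 2)
  fp <- place_electrode_array(g, electrode_array_spec(spacing = 20))
  pc <- footprint_coords(g, fp)
  expect_named(pc, c("C1", "M1", "M2", "C2"))
  expect_equal(mean(pc$M1[, "z_mm"]), -10)
  expect_equal(mean(pc$M2[, "z_mm"]), 10)
})
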