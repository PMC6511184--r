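test_that("boundary formulas reproduce the hand arithmetic", {
  s <- flat_surfaces(100, 410)
  b <- derive_boundaries(s)
  expect_true(all(b$z_opl == 300))
  expect_true(all(b$t_ilm_opl == 200))
  expect_true(all(b$z_ipl == 240))
  expect_true(all(b$cc_inner == 439))
  expect_true(all(b$cc_outer == 459))
  expect_true(validate_segmentation(b, s)$ok)

  # degenerate: ILM at 0, RPE at exactly the OPL offset -> SCP slab collapses
  s0 <- flat_surfaces(0, 110)
  b0 <- derive_boundaries(s0)
  expect_true(all(b0$z_opl == 0) && all(b0$z_ipl == 0) && all(b0$t_ilm_opl == 0))

  # inverted: boundaries still computed, QC must flag the ordering
  si <- flat_surfaces(50, 150)
  bi <- derive_boundaries(si)
  expect_true(all(bi$z_opl == 40))   # above the ILM
  qc <- validate_segmentation(bi, si)
  expect_false(qc$ok)
  expect_match(qc$reason, "ordering")
  expect_true(all(qc$violation_mask))
})

test_that("QC flags exactly the corrupted A-scans", {
  s <- flat_surfaces(100, 410, n_px = 8)
  s$z_rpe[3, 5] <- 150  # single corrupted A-scan
  qc <- validate_segmentation(derive_boundaries(s), s)
  expect_false(qc$ok)
  expect_identical(sum(qc$violation_mask), 1L)
  expect_true(qc$violation_mask[3, 5])

  s$z_ilm[1, 1] <- -5   # negative boundary
  qc2 <- validate_segmentation(derive_boundaries(s), s)
  expect_identical(sum(qc2$violation_mask), 2L)
  expect_match(qc2$reason, "negative")
})

test_that("translation equivariance, CC thickness and slab nesting hold on random eyes", {
  g <- scan_geometry(6, n_px = 20)
  for (seed in 1:5) {
    s <- generate_surfaces(g, foveal_pit_depth_um = 70, vmt_peak_um = 40,
                           vmt_diameter_um = 900, seed = seed)
    b <- derive_boundaries(s)
    expect_true(all(abs(b$cc_outer - b$cc_inner - 20) < 1e-12))
    # SCP [ilm, ipl) and DCP [ipl, opl) tile [ilm, opl)
    expect_true(all(s$z_ilm <= b$z_ipl & b$z_ipl <= b$z_opl))

    cshift <- 37.5
    s2 <- surface_set(s$z_ilm + cshift, s$z_rpe + cshift, g)
    b2 <- derive_boundaries(s2)
    for (f in c("z_ipl", "z_opl", "cc_inner", "cc_outer")) {
      expect_equal(b2[[f]], b[[f]] + cshift, tolerance = 1e-9)
    }
    expect_equal(b2$t_ilm_opl, b$t_ilm_opl, tolerance = 1e-9)
  }
})

test_that("mismatched surface grids are rejected", {
  g <- scan_geometry(6, n_px = 4)
  expect_error(surface_set(matrix(100, 4, 4), matrix(400, 5, 5), g),
               "dimensions")
})

test_that("slab projection aggregates the correct voxels", {
  n <- 4
  s <- flat_surfaces(100, 410, n_px = n)      # SCP [100, 240), DCP [240, 300)
  b <- derive_boundaries(s)
  nz <- 50                                     # voxel centres at 5, 15, ..., 495
  vol <- array(7, dim = c(n, n, nz))
  expect_true(all(project_slab(vol, b, s, "SCP", "max") == 7))
  expect_true(all(project_slab(vol, b, s, "DCP", "mean") == 7))

  # single bright voxel at depth 155 um -> SCP only
  vol2 <- array(0, dim = c(n, n, nz))
  vol2[2, 3, 16] <- 255                        # centre depth 155
  expect_identical(project_slab(vol2, b, s, "SCP", "max")[2, 3], 255)
  expect_identical(max(project_slab(vol2, b, s, "DCP", "max")), 0)
  expect_identical(max(project_slab(vol2, b, s, "CC", "max")), 0)

  # half-covered two-valued column: DCP spans 6 voxels (245..295), set 3 to 255
  vol3 <- array(0, dim = c(n, n, nz))
  vol3[1, 1, 25:27] <- 255                     # depths 245, 255, 265
  expect_identical(project_slab(vol3, b, s, "DCP", "mean")[1, 1], 127.5)
  expect_identical(project_slab(vol3, b, s, "DCP", "max")[1, 1], 255)

  # slab entirely outside the sampled depth range
  shallow <- array(1, dim = c(n, n, 5))        # depths 5..45
  expect_error(project_slab(shallow, b, s, "CC"), "outside the volume")
})
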