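test_that("shoelace area matches hand values and the regular-polygon closed form", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_identical(polygon_area(sq), 1.0)
  expect_identical(polygon_area(cbind(c(0, 1, 0), c(0, 0, 1))), 0.5)
  # orientation independence
  expect_identical(polygon_area(sq[4:1, ]), 1.0)

  # closed-form oracle: area of a regular n-gon = n R^2 sin(2 pi / n) / 2
  for (n in c(12, 64, 256)) {
    R <- 0.75
    expect_equal(polygon_area(regular_polygon(n, R)),
                 0.5 * n * R^2 * sin(2 * pi / n), tolerance = 1e-12)
  }
  # the 64-gon approaches the pi r^2 of a maximal 1500-um adhesion disk
  expect_lt(abs(polygon_area(regular_polygon(64, 0.75)) - pi * 0.75^2), 0.005)
})

test_that("area is exactly scale- and translation-equivariant", {
  set.seed(11)
  v <- regular_polygon(9, 0.4) + matrix(rnorm(18, 0, 0.03), 9, 2)
  a <- polygon_area(v)
  for (k in c(0.5, 2, 7.3)) {
    expect_equal(polygon_area(v * k), a * k^2, tolerance = 1e-12)
  }
  expect_equal(polygon_area(cbind(v[, 1] + 5, v[, 2] - 2.25)), a,
               tolerance = 1e-9)
})

test_that("degenerate and self-intersecting polygons are handled", {
  expect_warning(a <- polygon_area(cbind(c(0, 1), c(0, 1))), "fewer than 3")
  expect_identical(a, 0)
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(polygon_area(bowtie), "self-intersecting")
  expect_error(faz_region(bowtie), "self-intersecting")
  expect_identical(faz_region(NULL)$area_mm2, 0)
})

test_that("faz_region area agrees with the shoelace to 1e-9", {
  v <- regular_polygon(12, 0.2, center = c(1.5, 1.5))
  faz <- faz_region(v)
  expect_lt(abs(faz$area_mm2 - polygon_area(v)), 1e-9)
})

test_that("rasterization: exact count for an aligned square, empty cases", {
  # 100 x 100 grid over 1 mm: pixel centres at 0, 0.01, ..., 0.99 mm; this
  # square contains exactly the 50 x 50 block of centres 0.25..0.74 mm
  g <- scan_geometry(1, n_px = 100)
  sq <- faz_region(cbind(c(0.245, 0.745, 0.745, 0.245),
                         c(0.245, 0.245, 0.745, 0.745)))
  r <- rasterize_faz(sq, g)
  expect_identical(sum(r), 2500L)

  expect_identical(sum(rasterize_faz(faz_region(NULL), g)), 0L)
  far <- faz_region(regular_polygon(8, 0.1, center = c(50, 50)))
  expect_warning(r2 <- rasterize_faz(far, g), "outside the scan")
  expect_false(any(r2))
})

test_that("pixel-centre rule agrees with an independent winding-number oracle", {
  g <- scan_geometry(3, n_px = 30)
  set.seed(42)
  v <- regular_polygon(10, 0.9, center = c(1.5, 1.5)) +
    matrix(rnorm(20, 0, 0.05), 10, 2)
  r <- rasterize_faz(faz_region(v), g)
  pc <- pixel_centers(g)
  for (i in seq_len(30)) {
    for (j in seq_len(30)) {
      expect_identical(r[i, j], oracle_inside(pc$x[j], pc$y[i], v))
    }
  }
})

test_that("raster area converges to the shoelace area with grid refinement", {
  faz <- synthetic_faz_polygon(0.103, c(3, 3), seed = 5)
  err <- sapply(c(100, 350), function(n) {
    g <- scan_geometry(6, n_px = n)
    abs(sum(rasterize_faz(faz, g)) * g$px_scale_mm^2 - faz$area_mm2)
  })
  expect_lt(err[2] / 0.103, 0.02)  # within 2% at the 6x6 preset
  expect_lt(err[2], err[1])        # refinement reduces the error
})

test_that("FAZ JSON round-trips and synthetic polygons hit their target area", {
  faz <- synthetic_faz_polygon(0.198, c(3, 3), seed = 9)
  expect_lt(abs(faz$area_mm2 - 0.198), 1e-9)
  expect_identical(faz$vertices_mm,
                   synthetic_faz_polygon(0.198, c(3, 3), seed = 9)$vertices_mm)
  path <- tempfile(fileext = ".json")
  write_faz(faz, path)
  back <- read_faz(path)
  expect_equal(back$vertices_mm, faz$vertices_mm, tolerance = 1e-12)
  expect_equal(back$area_mm2, faz$area_mm2, tolerance = 1e-12)
})
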